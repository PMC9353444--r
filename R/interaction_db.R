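#' Load a protein-interaction database
#'
#' Reads a tab-separated interaction table into an indexed database of
#' gene-pair records. Each record carries per-channel evidence scores,
#' a combined credibility score on the 1-1000 scale (binned into four
#' confidence levels at 400/700/900, see [credibility_level()]), and zero
#' or more action records describing the functional interplay of the pair
#' (one of 8 modes) and the direction of expression influence (one of 4
#' effects).
#'
#' Expected columns: `gene_a`, `gene_b`, one integer column per evidence
#' channel (see [evidence_channels()]; missing channel columns are treated
#' as all-zero), `credibility`, and `actions` — semicolon-joined tokens of
#' the form `mode|effect|directional|acting_partner` where `directional`
#' is `t`/`f` and `acting_partner` is `a`, `b` or `unknown`. Gzip is
#' accepted.
#'
#' Three evidence-class flags are derived from the channels, mirroring the
#' three sub-databases used for benchmarking: `experiment_validated`
#' (experiments > 0), `pathway_curated` (database > 0) and `predicted`
#' (any other channel > 0). The flags are not mutually exclusive.
#'
#' @param path path to the interaction table (TSV, optionally gzipped).
#' @param species `"human"` or `"mouse"` for symbol normalization.
#' @return an object of class `interaction_db`.
#' @seealso [subset_interactions()], [match_pair()]
#' @export
load_interaction_db <- function(path, species = c("human", "mouse")) {
  species <- match.arg(species)
  tab <- read_tsv(path)
  check_columns(tab, c("gene_a", "gene_b", "credibility", "actions"),
                "interaction table")
  if (nrow(tab) == 0L) validation_error("interaction table is empty")
  tab$gene_a <- normalize_symbols(tab$gene_a, species)
  tab$gene_b <- normalize_symbols(tab$gene_b, species)

  chan_names <- evidence_channels()
  channels <- matrix(0L, nrow(tab), length(chan_names),
                     dimnames = list(NULL, chan_names))
  for (ch in intersect(chan_names, names(tab))) {
    v <- suppressWarnings(as.numeric(tab[[ch]]))
    v[is.na(v)] <- 0
    if (any(v < 0)) {
      validation_error("negative evidence score in channel '", ch, "'")
    }
    channels[, ch] <- as.integer(v)
  }

  cred <- suppressWarnings(as.numeric(tab$credibility))
  if (any(is.na(cred) | cred < 1 | cred > 1000)) {
    validation_error("credibility outside [1,1000] at row ",
                     which(is.na(cred) | cred < 1 | cred > 1000)[1L])
  }

  # canonical unordered storage: gene_a <= gene_b lexicographically
  swap <- tab$gene_a > tab$gene_b
  a <- ifelse(swap, tab$gene_b, tab$gene_a)
  b <- ifelse(swap, tab$gene_a, tab$gene_b)
  pair_id <- paste(a, b, sep = "|")
  if (anyDuplicated(pair_id)) {
    validation_error("duplicate gene pair '", pair_id[duplicated(pair_id)][1L],
                     "' in interaction table")
  }

  other <- setdiff(chan_names, c("experiments", "database"))
  interactions <- data.frame(
    pair_id = pair_id, gene_a = a, gene_b = b,
    credibility = as.integer(cred),
    confidence_level = credibility_level(cred),
    experiment_validated = channels[, "experiments"] > 0L,
    pathway_curated = channels[, "database"] > 0L,
    predicted = rowSums(channels[, other, drop = FALSE]) > 0L,
    stringsAsFactors = FALSE
  )

  actions <- parse_actions(tab$actions, pair_id, swap)

  structure(list(species = species, interactions = interactions,
                 channels = channels, actions = actions),
            class = "interaction_db")
}

# action tokens: mode|effect|directional(t/f)|acting_partner(a/b/unknown)
parse_actions <- function(raw, pair_id, swap) {
  raw <- trimws(as.character(raw))
  toks <- strsplit(raw, ";", fixed = TRUE)
  n_each <- lengths(toks)
  flat <- trimws(unlist(toks, use.names = FALSE))
  rid <- rep(seq_along(raw), n_each)
  keep <- nzchar(flat)
  flat <- flat[keep]; rid <- rid[keep]
  if (!length(flat)) {
    return(data.frame(pair_id = character(), mode = character(),
                      effect = character(), is_directional = logical(),
                      acting_partner = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(flat, "|", fixed = TRUE)
  if (any(lengths(parts) != 4L)) {
    validation_error("malformed action token '",
                     flat[lengths(parts) != 4L][1L],
                     "' (expected mode|effect|directional|acting_partner)")
  }
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  mode <- m[, 1L]; effect <- m[, 2L]; dirc <- m[, 3L]; who <- m[, 4L]
  if (any(!mode %in% action_modes())) {
    validation_error("unknown action mode '",
                     mode[!mode %in% action_modes()][1L], "'")
  }
  if (any(!effect %in% action_effects())) {
    validation_error("unknown action effect '",
                     effect[!effect %in% action_effects()][1L], "'")
  }
  if (any(!dirc %in% c("t", "f"))) {
    validation_error("action directional flag must be 't' or 'f'")
  }
  if (any(!who %in% c("a", "b", "unknown"))) {
    validation_error("acting_partner must be 'a', 'b' or 'unknown'")
  }
  is_dir <- dirc == "t"
  if (any(effect == "undirected" & is_dir)) {
    validation_error("an 'undirected' effect cannot be directional")
  }
  # acting_partner refers to the columns as written; remap after canonical swap
  swapped <- swap[rid]
  who[swapped & who == "a"] <- "B"
  who[swapped & who == "b"] <- "a"
  who[who == "B"] <- "b"
  out <- data.frame(pair_id = pair_id[rid], mode = mode, effect = effect,
                    is_directional = is_dir, acting_partner = who,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.interaction_db <- function(x, ...) {
  cat("<interaction_db> ", nrow(x$interactions), " ", x$species,
      " gene pairs; ", nrow(x$actions), " action records\n", sep = "")
  invisible(x)
}

#' Write an interaction database back to its table format
#'
#' @param db an `interaction_db`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interaction_db <- function(db, path) {
  stopifnot(inherits(db, "interaction_db"))
  ints <- db$interactions
  act_str <- vapply(ints$pair_id, function(pid) {
    a <- db$actions[db$actions$pair_id == pid, , drop = FALSE]
    if (nrow(a) == 0L) return("")
    paste(paste(a$mode, a$effect, ifelse(a$is_directional, "t", "f"),
                a$acting_partner, sep = "|"), collapse = ";")
  }, character(1L))
  out <- data.frame(gene_a = ints$gene_a, gene_b = ints$gene_b,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(db$channels))
  out$credibility <- ints$credibility
  out$actions <- act_str
  write_tsv(out, path)
}

#' Interaction filter
#'
#' Builds the filter used by [subset_interactions()]. All constraints are
#' optional; an empty filter keeps the database unchanged.
#'
#' @param evidence evidence classes to require (any-of):
#'   `"experiment_validated"`, `"pathway_curated"`, `"predicted"`.
#' @param min_level minimum confidence level (`"low"` < `"medium"` <
#'   `"high"` < `"highest"`); translated to the credibility cutoffs
#'   1/400/700/900.
#' @param min_credibility raw credibility threshold in \[1,1000\];
#'   alternative to `min_level`.
#' @param modes,effects allowed action modes / effects (any-of). A record
#'   survives only if at least one of its action records matches both, and
#'   it is stripped to the matching actions. An explicitly empty set is a
#'   contradictory filter and an error.
#' @return an object of class `interaction_filter`.
#' @export
interaction_filter <- function(evidence = NULL, min_level = NULL,
                               min_credibility = NULL, modes = NULL,
                               effects = NULL) {
  if (!is.null(evidence)) {
    bad <- setdiff(evidence, evidence_classes())
    if (length(bad)) {
      validation_error("unknown evidence class: ", paste(bad, collapse = ", "))
    }
    if (!length(evidence)) validation_error("empty evidence-class set")
  }
  if (!is.null(min_level)) {
    if (length(min_level) != 1L || !min_level %in% confidence_levels()) {
      validation_error("min_level must be one of: ",
                       paste(confidence_levels(), collapse = ", "))
    }
  }
  if (!is.null(min_credibility) &&
      (min_credibility < 1 || min_credibility > 1000)) {
    validation_error("min_credibility must lie in [1,1000]")
  }
  if (!is.null(modes)) {
    if (!length(modes)) validation_error("empty action-mode set")
    bad <- setdiff(modes, action_modes())
    if (length(bad)) {
      validation_error("unknown action mode: ", paste(bad, collapse = ", "))
    }
  }
  if (!is.null(effects)) {
    if (!length(effects)) validation_error("empty action-effect set")
    bad <- setdiff(effects, action_effects())
    if (length(bad)) {
      validation_error("unknown action effect: ", paste(bad, collapse = ", "))
    }
  }
  structure(list(evidence = evidence, min_level = min_level,
                 min_credibility = min_credibility, modes = modes,
                 effects = effects),
            class = "interaction_filter")
}

level_cutoff <- function(level) {
  c(low = 1, medium = 400, high = 700, highest = 900)[[level]]
}

#' Subset an interaction database
#'
#' Restricts a database to records matching an [interaction_filter()]: a
#' record survives iff its evidence-class flags intersect the requested
#' classes, its credibility passes the threshold, and at least one of its
#' action records matches both the mode and the effect constraint.
#' Surviving records keep only the matching action records. The operation
#' is idempotent, and tighter filters always yield subsets.
#'
#' @param db an `interaction_db`.
#' @param filter an `interaction_filter`.
#' @return a filtered `interaction_db`.
#' @export
subset_interactions <- function(db, filter = interaction_filter()) {
  stopifnot(inherits(db, "interaction_db"))
  if (!inherits(filter, "interaction_filter")) {
    validation_error("filter must be built with interaction_filter()")
  }
  ints <- db$interactions
  keep <- rep(TRUE, nrow(ints))
  if (!is.null(filter$evidence)) {
    flags <- as.matrix(ints[, evidence_classes(), drop = FALSE])
    keep <- keep & rowSums(flags[, filter$evidence, drop = FALSE]) > 0
  }
  cut <- filter$min_credibility
  if (!is.null(filter$min_level)) {
    cut <- max(cut %||% 1, level_cutoff(filter$min_level))
  }
  if (!is.null(cut)) keep <- keep & ints$credibility >= cut

  acts <- db$actions
  if (!is.null(filter$modes) || !is.null(filter$effects)) {
    ok <- rep(TRUE, nrow(acts))
    if (!is.null(filter$modes)) ok <- ok & acts$mode %in% filter$modes
    if (!is.null(filter$effects)) ok <- ok & acts$effect %in% filter$effects
    acts <- acts[ok, , drop = FALSE]
    keep <- keep & ints$pair_id %in% acts$pair_id
  }
  ints <- ints[keep, , drop = FALSE]
  rownames(ints) <- NULL
  acts <- acts[acts$pair_id %in% ints$pair_id, , drop = FALSE]
  rownames(acts) <- NULL
  structure(list(species = db$species, interactions = ints,
                 channels = db$channels[keep, , drop = FALSE],
                 actions = acts),
            class = "interaction_db")
}

#' Look up the interaction record(s) for a gene pair
#'
#' Pairs are stored unordered, so querying (A, B) finds a record stored as
#' (B, A); the returned object carries orientation metadata recording which
#' query gene is the sender. An absent pair yields an empty match, not an
#' error.
#'
#' @param db an `interaction_db`.
#' @param sender_gene,receiver_gene gene symbols (already normalized).
#' @return a list with elements `interactions` (matching rows), `actions`
#'   (their action records), `sender_gene` and `receiver_gene`.
#' @export
match_pair <- function(db, sender_gene, receiver_gene) {
  stopifnot(inherits(db, "interaction_db"))
  key <- paste(min(sender_gene, receiver_gene),
               max(sender_gene, receiver_gene), sep = "|")
  hit <- db$interactions[db$interactions$pair_id == key, , drop = FALSE]
  rownames(hit) <- NULL
  acts <- db$actions[db$actions$pair_id %in% hit$pair_id, , drop = FALSE]
  rownames(acts) <- NULL
  list(interactions = hit, actions = acts,
       sender_gene = sender_gene, receiver_gene = receiver_gene)
}
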
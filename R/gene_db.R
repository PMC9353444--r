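#' Load a gene annotation database
#'
#' Reads a tab-separated gene annotation table into an indexed database of
#' gene records. Each gene carries zero or more subcellular localization
#' annotations (one of 13 fixed categories, with an integer confidence in
#' 1-5), a set of functional classes from the bundled 132-class taxonomy
#' (each class belonging to one of 16 groups), and a set of GO identifiers.
#'
#' The expected columns are `symbol`, `species`, `loc_category`,
#' `loc_confidence`, `function_class` and `go_terms` (semicolon-joined GO
#' ids), one row per (symbol, localization, class) combination; empty
#' `loc_category` or `function_class` cells mean "no annotation from this
#' row". Gzip-compressed files are accepted. Rows whose localization
#' category or functional class falls outside the closed vocabularies are
#' rejected with an error (never silently dropped). Duplicate
#' (symbol, category) localization rows collapse to the maximum confidence,
#' since repeated evidence for a compartment can only strengthen it.
#'
#' @param path path to the annotation table (TSV, optionally gzipped).
#' @param species `"human"` or `"mouse"`; rows for other species are an
#'   error. Symbols are case-normalized per species conventions.
#' @param taxonomy class-to-group mapping data.frame; defaults to the
#'   bundled taxonomy ([function_taxonomy()]).
#' @return an object of class `gene_db`.
#' @seealso [select_genes()], [write_gene_db()]
#' @export
load_gene_db <- function(path, species = c("human", "mouse"),
                         taxonomy = function_taxonomy()) {
  species <- match.arg(species)
  tab <- read_tsv(path)
  check_columns(tab, c("symbol", "species", "loc_category", "loc_confidence",
                       "function_class", "go_terms"),
                "gene annotation table")
  if (nrow(tab) == 0L) validation_error("gene annotation table is empty")
  tab$species <- tolower(trimws(tab$species))
  wrong <- tab$species != species
  if (any(wrong)) {
    validation_error("table contains rows for species other than '", species,
                     "' (first at row ", which(wrong)[1L], ")")
  }
  tab$symbol <- normalize_symbols(tab$symbol, species)
  if (any(!nzchar(tab$symbol))) {
    validation_error("empty gene symbol at row ",
                     which(!nzchar(tab$symbol))[1L])
  }

  tab$loc_category <- trimws(as.character(tab$loc_category))
  has_loc <- nzchar(tab$loc_category)
  bad_cat <- has_loc & !(tab$loc_category %in% localization_categories())
  if (any(bad_cat)) {
    validation_error("unknown localization category '",
                     tab$loc_category[bad_cat][1L], "' at row ",
                     which(bad_cat)[1L])
  }
  conf <- suppressWarnings(as.numeric(tab$loc_confidence))
  bad_conf <- has_loc & (is.na(conf) | conf < 1 | conf > 5 | conf != round(conf))
  if (any(bad_conf)) {
    validation_error("localization confidence outside [1,5] at row ",
                     which(bad_conf)[1L])
  }

  tab$function_class <- trimws(as.character(tab$function_class))
  has_fun <- nzchar(tab$function_class)
  bad_fun <- has_fun & !(tab$function_class %in% taxonomy$class)
  if (any(bad_fun)) {
    validation_error("unknown functional class '",
                     tab$function_class[bad_fun][1L], "' at row ",
                     which(bad_fun)[1L])
  }

  loc <- tab[has_loc, c("symbol", "loc_category")]
  loc$confidence <- as.integer(conf[has_loc])
  names(loc)[2L] <- "category"
  if (nrow(loc)) {
    # duplicate (symbol, category) rows collapse to the max confidence
    key <- paste(loc$symbol, loc$category, sep = "\r")
    loc <- loc[order(key, -loc$confidence), ]
    loc <- loc[!duplicated(paste(loc$symbol, loc$category, sep = "\r")), ]
    rownames(loc) <- NULL
  }

  fun <- unique(tab[has_fun, c("symbol", "function_class")])
  names(fun)[2L] <- "class"
  fun$group <- taxonomy$group[match(fun$class, taxonomy$class)]
  fun <- fun[order(fun$symbol, fun$class), ]
  rownames(fun) <- NULL

  go_raw <- trimws(as.character(tab$go_terms))
  go_list <- strsplit(go_raw, ";", fixed = TRUE)
  go <- data.frame(
    symbol = rep(tab$symbol, lengths(go_list)),
    go_term = trimws(unlist(go_list, use.names = FALSE)),
    stringsAsFactors = FALSE
  )
  go <- unique(go[nzchar(go$go_term), , drop = FALSE])
  bad_go <- !grepl("^GO:\\d{7}$", go$go_term)
  if (any(bad_go)) {
    validation_error("malformed GO identifier '", go$go_term[bad_go][1L], "'")
  }
  go <- go[order(go$symbol, go$go_term), , drop = FALSE]
  rownames(go) <- NULL

  structure(
    list(species = species,
         symbols = sort(unique(tab$symbol)),
         localizations = loc,
         functions = fun,
         go = go,
         taxonomy = taxonomy),
    class = "gene_db"
  )
}

#' @export
print.gene_db <- function(x, ...) {
  cat("<gene_db> ", length(x$symbols), " ", x$species, " genes; ",
      nrow(x$localizations), " localization, ", nrow(x$functions),
      " functional, ", nrow(x$go), " GO annotations\n", sep = "")
  invisible(x)
}

#' Write a gene database back to its table format
#'
#' Serializes a `gene_db` to the same TSV schema accepted by
#' [load_gene_db()], so that load -> write -> load round-trips to an
#' identical database.
#'
#' @param db a `gene_db`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_db <- function(db, path) {
  stopifnot(inherits(db, "gene_db"))
  rows <- lapply(db$symbols, function(s) {
    loc <- db$localizations[db$localizations$symbol == s, , drop = FALSE]
    fun <- db$functions[db$functions$symbol == s, , drop = FALSE]
    go <- paste(db$go$go_term[db$go$symbol == s], collapse = ";")
    if (nrow(loc) == 0L) loc <- data.frame(category = "", confidence = NA)
    if (nrow(fun) == 0L) fun <- data.frame(class = "")
    grid <- expand.grid(i = seq_len(nrow(loc)), j = seq_len(nrow(fun)))
    data.frame(symbol = s, species = db$species,
               loc_category = loc$category[grid$i],
               loc_confidence = loc$confidence[grid$i],
               function_class = fun$class[grid$j],
               go_terms = go, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$loc_confidence[is.na(out$loc_confidence)] <- ""
  write_tsv(out, path)
}

#' Gene selection filter
#'
#' Builds the filter used by [select_genes()]. Constraints are optional and
#' combine conjunctively across the three annotation axes (localization AND
#' function AND GO membership), while lists within one axis are disjunctive
#' (a gene matches if ANY listed category/class/term applies to it). An
#' empty filter selects every gene.
#'
#' @param categories localization categories to require (any-of); `NULL`
#'   for no localization constraint.
#' @param min_confidence minimum localization confidence (1-5) a matching
#'   annotation must reach. Defaults to 4, the recommended cutoff keeping
#'   only confidently placed proteins (confidence 4 and 5).
#' @param groups,classes functional groups / fine-grained classes (any-of).
#' @param go_terms GO identifiers (any-of).
#' @return an object of class `gene_filter`.
#' @export
gene_filter <- function(categories = NULL, min_confidence = 4L,
                        groups = NULL, classes = NULL, go_terms = NULL) {
  if (!is.null(categories)) {
    bad <- setdiff(categories, localization_categories())
    if (length(bad)) {
      validation_error("unknown localization category in filter: ",
                       paste(bad, collapse = ", "))
    }
  }
  if (!is.numeric(min_confidence) || length(min_confidence) != 1L ||
      min_confidence < 1 || min_confidence > 5) {
    validation_error("min_confidence must be a single value in [1,5]")
  }
  if (!is.null(groups)) {
    bad <- setdiff(groups, function_groups())
    if (length(bad)) {
      validation_error("unknown functional group in filter: ",
                       paste(bad, collapse = ", "))
    }
  }
  structure(list(categories = categories,
                 min_confidence = as.numeric(min_confidence),
                 groups = groups, classes = classes, go_terms = go_terms),
            class = "gene_filter")
}

#' Select genes satisfying annotation constraints
#'
#' Applies a [gene_filter()] to a gene database and returns the symbols
#' satisfying all provided constraints. The localization constraint is met
#' if ANY of the gene's annotations carries a listed category with
#' confidence at least `min_confidence`; the functional constraint if any
#' of its classes (or the class's group) is listed; the GO constraint if
#' the gene carries any listed term. Relaxing the confidence cutoff or
#' adding categories can therefore never shrink the result.
#'
#' @param db a `gene_db`.
#' @param filter a `gene_filter`; the default empty filter selects all
#'   genes.
#' @return sorted character vector of selected symbols.
#' @examples
#' \dontrun{
#' select_genes(db, gene_filter(categories = "plasma membrane",
#'                              groups = "receptor"))
#' }
#' @export
select_genes <- function(db, filter = gene_filter(min_confidence = 1L)) {
  stopifnot(inherits(db, "gene_db"))
  if (!inherits(filter, "gene_filter")) {
    validation_error("filter must be built with gene_filter()")
  }
  if (!is.null(filter$classes)) {
    bad <- setdiff(filter$classes, db$taxonomy$class)
    if (length(bad)) {
      validation_error("unknown functional class in filter: ",
                       paste(bad, collapse = ", "))
    }
  }
  keep <- db$symbols
  if (!is.null(filter$categories)) {
    loc <- db$localizations
    ok <- loc$category %in% filter$categories &
      loc$confidence >= filter$min_confidence
    keep <- intersect(keep, unique(loc$symbol[ok]))
  }
  if (!is.null(filter$groups) || !is.null(filter$classes)) {
    fun <- db$functions
    ok <- rep(FALSE, nrow(fun))
    if (!is.null(filter$groups)) ok <- ok | fun$group %in% filter$groups
    if (!is.null(filter$classes)) ok <- ok | fun$class %in% filter$classes
    keep <- intersect(keep, unique(fun$symbol[ok]))
  }
  if (!is.null(filter$go_terms)) {
    ok <- db$go$go_term %in% filter$go_terms
    keep <- intersect(keep, unique(db$go$symbol[ok]))
  }
  sort(keep)
}
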
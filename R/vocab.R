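#' Controlled vocabularies of the annotation schema
#'
#' The annotation model uses closed vocabularies throughout: a 13-category
#' subcellular localization scheme, a 132-class functional taxonomy grouped
#' into 16 groups, 8 protein-interaction action modes, 4 action effects, and
#' a fixed set of interaction evidence channels. Loaders reject any token
#' outside these sets; there is no free-text annotation.
#'
#' @return Character vectors of the allowed tokens, or for
#'   [function_taxonomy()] a data.frame with columns `class` and `group`.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
localization_categories <- function() {
  c("extracellular region", "plasma membrane", "cytosol", "cytoskeleton",
    "peroxisome", "lysosome", "endoplasmic reticulum", "Golgi apparatus",
    "endosome", "mitochondrion", "cytoplasm", "nucleus", "other")
}

#' @rdname vocabularies
#' @export
function_groups <- function() {
  c("actin-binding and motor protein", "antimicrobial", "cytokine", "enzyme",
    "growth factor", "hormone", "hydrolase", "ion channel",
    "protein metabolism regulator", "receptor", "transcription regulator",
    "transducer", "transferase", "translation regulator", "vasoactive",
    "other")
}

#' @rdname vocabularies
#' @export
action_modes <- function() {
  c("activation", "binding", "catalysis", "expression", "inhibition",
    "ptmod", "reaction", "other")
}

#' @rdname vocabularies
#' @export
action_effects <- function() {
  c("positive", "negative", "unspecified", "undirected")
}

#' @rdname vocabularies
#' @export
evidence_channels <- function() {
  c("experiments", "experiments_transferred",
    "database", "database_transferred",
    "neighborhood", "neighborhood_transferred",
    "fusion", "cooccurence", "homology",
    "coexpression", "coexpression_transferred",
    "textmining", "textmining_transferred")
}

#' @rdname vocabularies
#' @export
evidence_classes <- function() {
  c("experiment_validated", "pathway_curated", "predicted")
}

#' @rdname vocabularies
#' @export
confidence_levels <- function() {
  c("low", "medium", "high", "highest")
}

# cache for the bundled taxonomy table
.taxonomy_env <- new.env(parent = emptyenv())

#' @rdname vocabularies
#' @param path optional path to a class-to-group mapping TSV; defaults to the
#'   taxonomy bundled with the package.
#' @export
function_taxonomy <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.taxonomy_env$tab)) return(.taxonomy_env$tab)
    path <- system.file("extdata", "function_taxonomy.tsv",
                        package = "cellxtalk", mustWork = TRUE)
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("class", "group") %in% names(tab))) {
    stop("taxonomy file must have columns 'class' and 'group'", call. = FALSE)
  }
  if (anyDuplicated(tab$class)) {
    stop("taxonomy classes must be unique", call. = FALSE)
  }
  bad <- setdiff(unique(tab$group), function_groups())
  if (length(bad)) {
    stop("unknown taxonomy group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (cache) .taxonomy_env$tab <- tab
  tab
}

#' Bin a credibility score into a confidence level
#'
#' Interaction credibility is scored on a 1-1000 scale and binned into four
#' confidence levels at the fixed cutoffs 400 / 700 / 900: `highest` for
#' scores >= 900, `high` for 700-899, `medium` for 400-699 and `low` below
#' 400. The bins partition the full range, so every valid score maps to
#' exactly one level.
#'
#' @param credibility integer vector of scores in \[1, 1000\].
#' @return character vector of levels (`"low"`, `"medium"`, `"high"`,
#'   `"highest"`).
#' @examples
#' credibility_level(c(150, 400, 700, 900, 1000))
#' @export
credibility_level <- function(credibility) {
  if (any(is.na(credibility)) || any(credibility < 1 | credibility > 1000)) {
    stop("credibility scores must lie in [1, 1000]", call. = FALSE)
  }
  lv <- character(length(credibility))
  lv[credibility < 400] <- "low"
  lv[credibility >= 400 & credibility < 700] <- "medium"
  lv[credibility >= 700 & credibility < 900] <- "high"
  lv[credibility >= 900] <- "highest"
  lv
}
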
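`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Normalize gene symbols for a species
#'
#' Symbol casing differs between the human (all upper-case, e.g. `IL6`) and
#' mouse (first letter capitalized, e.g. `Il6`) conventions; inputs from
#' different tools often disagree. All loaders normalize symbols with this
#' rule before matching, so that e.g. a DEG table in mixed case still joins
#' against the annotation database.
#'
#' @param symbols character vector of gene symbols.
#' @param species `"human"` or `"mouse"`.
#' @return normalized character vector.
#' @export
normalize_symbols <- function(symbols, species = c("human", "mouse")) {
  species <- match.arg(species)
  symbols <- trimws(as.character(symbols))
  if (species == "human") return(toupper(symbols))
  low <- tolower(symbols)
  paste0(toupper(substr(low, 1L, 1L)), substr(low, 2L, nchar(low)))
}

# stop() with a consistent validation-error class so callers can test for it
validation_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("cellxtalk_validation_error",
                                             "error", "condition")))
}

schema_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("cellxtalk_schema_error",
                                             "error", "condition")))
}

check_columns <- function(tab, required, what) {
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    schema_error(what, " is missing mandatory column(s): ",
                 paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) {
    validation_error("file not found: ", path)
  }
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
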
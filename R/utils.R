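#' @keywords internal
#' @importFrom stats rbinom quantile runif aggregate reshape
#' @importFrom utils read.delim write.table head packageVersion
#' @importFrom tools md5sum
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded internals do not
#' perturb the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Read a tab-separated table with a header
#' @noRd
read_tsv_strict <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""), quote = "",
                          comment.char = "")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' Write a table as deterministic TSV
#'
#' Numeric columns are formatted at 12 significant digits so repeated writes
#' of the same object are byte-identical.
#' @noRd
write_tsv_det <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- vapply(out[[j]], function(v)
        if (is.na(v)) NA_character_ else format(v, digits = 12, trim = TRUE,
                                                scientific = NA),
        character(1))
    if (is.logical(out[[j]])) out[[j]] <- ifelse(out[[j]], "TRUE", "FALSE")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Flat key = value configuration files
#'
#' Parses lines of the form `key = value`; blank lines and `#` comments are
#' ignored. Values that parse as numbers become numeric; comma-separated
#' values become character vectors.
#' @param path file to read.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (grepl(",", val, fixed = TRUE)) {
      val <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    }
    num <- suppressWarnings(as.numeric(val))
    if (length(val) && !anyNA(num)) val <- num
    out[[key]] <- val
  }
  out
}

assert_canonical_aa <- function(seq, what = "sequence",
                                allow = c("reject", "warn", "allow")) {
  allow <- match.arg(allow)
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", seq)
  if (any(bad) && allow != "allow") {
    msg <- paste0("non-canonical residue(s) in ", what, ": ",
                  paste(utils::head(seq[bad], 3), collapse = ", "))
    if (allow == "reject") stop(msg, call. = FALSE) else warning(msg,
                                                                call. = FALSE)
  }
  invisible(seq)
}
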
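#' Construct a trait matrix
#'
#' Per-sample values for the ten physiological traits with an explicit
#' missingness mask. Field campaigns rarely measure every trait on every leaf
#' (gas-exchange traits in particular are slow to acquire), so missing entries
#' are first-class: `NA` in `values` and `FALSE` in `mask` always coincide.
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param values Numeric matrix, one row per sample, columns named by
#'   [trait_names()] (any order accepted, stored canonically). `NA` marks a
#'   missing measurement.
#' @return An object of class `trait_matrix` with fields `sample_ids`,
#'   `values` and logical `mask` (`TRUE` where measured).
#' @export
trait_matrix <- function(sample_ids, values) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop_schema("sample ids must be unique")
  values <- as.matrix(values)
  if (nrow(values) != length(sample_ids))
    stop_schema("values has ", nrow(values), " rows for ", length(sample_ids),
                " sample ids")
  missing_traits <- setdiff(trait_names(), colnames(values))
  if (length(missing_traits))
    stop_schema("trait column(s) missing: ", paste(missing_traits, collapse = ", "))
  values <- values[, trait_names(), drop = FALSE]
  mask <- !is.na(values)
  if (nrow(values) > 0L && any(rowSums(mask) == 0L))
    stop_schema("sample(s) with no observed trait: ",
                paste(utils::head(sample_ids[rowSums(mask) == 0L], 5L), collapse = ", "))
  rownames(values) <- sample_ids
  structure(list(sample_ids = sample_ids, values = values, mask = mask),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("<trait_matrix> ", length(x$sample_ids), " sample(s); observed per trait: ",
      paste(colSums(x$mask), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Read a trait table CSV
#'
#' First column: sample id; remaining columns: the ten traits by canonical
#' name. Blank cells are missing measurements.
#'
#' @param path CSV path.
#' @return A [trait_matrix()].
#' @export
read_trait_csv <- function(path) {
  if (!file.exists(path)) stop_schema("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  trait_matrix(df[[1L]], as.matrix(df[, -1L, drop = FALSE]))
}

#' Write a trait table CSV
#'
#' @param tm A [trait_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trait_csv <- function(tm, path) {
  stopifnot(inherits(tm, "trait_matrix"))
  df <- cbind(data.frame(sample_id = tm$sample_ids),
              as.data.frame(tm$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
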
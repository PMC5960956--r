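# Plain-text table readers for the pipeline's external interfaces.

#' Read a measurement table (TSV)
#'
#' One row per observation with columns `treatment`, `replicate`,
#' `time_h`, `analyte`, `phase` (headspace/liquid), `value`, `unit`
#' (mol_fraction/mM), `pressure_kPa`, `temperature_K`, `pH`.
#'
#' @param path TSV file path.
#' @return validated data.frame in the [speciate()] input schema.
#' @export
read_measurements <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("treatment", "replicate", "time_h", "analyte", "phase",
           "value", "unit")
  missing <- setdiff(req, names(d))
  if (length(missing) > 0) {
    stop("measurement table ", sQuote(path), " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  d
}

#' Read a taxa-by-samples count table (TSV)
#'
#' First column taxon id, remaining columns integer counts per sample.
#'
#' @param path TSV file path.
#' @return integer matrix with taxon rownames.
#' @export
read_counts <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- d[[1]]
  .check_counts(m)
  m
}

#' Read a taxonomy map (TSV)
#'
#' Columns `taxon`, `phylum`, `family` (and optionally `phylotype`).
#' Empty rank entries are replaced by the `"unclassified"` sentinel.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_taxonomy <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!("taxon" %in% names(d))) stop("taxonomy needs a 'taxon' column")
  for (col in setdiff(names(d), "taxon")) {
    d[[col]][is.na(d[[col]]) | !nzchar(d[[col]])] <- "unclassified"
  }
  d
}

#' Read a phylotype similarity matrix (TSV)
#'
#' Square matrix with matching row/column phylotype labels, fractional
#' identities in `[0, 1]`, unit diagonal.
#'
#' @param path TSV file path.
#' @return numeric matrix.
#' @export
read_similarity <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- d[[1]]
  m
}
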
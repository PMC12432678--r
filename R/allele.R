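#' @keywords internal
"_PACKAGE"

# Loci with serology support. DRB1/3/4/5 share one DEP group; DQ/DP alpha
# chains are carried for genotype bookkeeping only.
SUPPORTED_LOCI <- c("A", "B", "C", "DRB1", "DRB3", "DRB4", "DRB5",
                    "DQA1", "DQB1", "DPA1", "DPB1")

#' Parse an HLA allele name
#'
#' Accepts WHO nomenclature with an optional \code{"HLA-"} prefix, e.g.
#' \code{"HLA-B*35:12"} or \code{"A*01:01"}. The locus and the colon-separated
#' integer fields are extracted; two to four fields are accepted (two fields
#' identify the protein, which is the resolution all serology operations work
#' at).
#'
#' @param raw A single allele name string.
#' @return An object of class \code{"hla_allele"} with elements \code{locus},
#'   \code{fields} (integer vector) and \code{raw}.
#' @examples
#' a <- parse_allele_name("HLA-B*35:12")
#' a$locus   # "B"
#' a$fields  # c(35, 12)
#' @export
parse_allele_name <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw))
    stop("allele name must be a single non-empty string", call. = FALSE)
  x <- trimws(raw)
  # tolerate the non-breaking hyphen that word processors insert
  x <- gsub("‐|‑|‒|–", "-", x)
  x <- sub("^HLA-", "", x, ignore.case = TRUE)
  if (!grepl("\\*", x))
    stop(sprintf("malformed allele name '%s': missing '*' between locus and fields", raw),
         call. = FALSE)
  parts <- strsplit(x, "*", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || !nzchar(parts[1L]))
    stop(sprintf("malformed allele name '%s': expected '<locus>*<fields>'", raw),
         call. = FALSE)
  locus <- toupper(parts[1L])
  if (!locus %in% SUPPORTED_LOCI)
    stop(sprintf("malformed allele name '%s': unsupported locus '%s'", raw, locus),
         call. = FALSE)
  field_str <- parts[2L]
  # drop a trailing expression suffix (N, L, S, C, A, Q) if present
  field_str <- sub("[NLSCAQ]$", "", field_str)
  fields <- strsplit(field_str, ":", fixed = TRUE)[[1L]]
  if (length(fields) < 2L || length(fields) > 4L || any(!grepl("^[0-9]+$", fields)))
    stop(sprintf("malformed allele name '%s': fields must be 2-4 colon-separated integers ('%s')",
                 raw, field_str), call. = FALSE)
  structure(list(locus = locus, fields = as.integer(fields), raw = raw),
            class = "hla_allele")
}

#' Render an allele name in canonical form
#'
#' @param x An \code{"hla_allele"} object.
#' @param n_fields Number of fields to render (default: all stored fields).
#' @return Canonical string such as \code{"B*35:12"} (no \code{"HLA-"} prefix,
#'   fields zero-padded to two digits).
#' @export
format_allele_name <- function(x, n_fields = length(x$fields)) {
  stopifnot(inherits(x, "hla_allele"))
  f <- x$fields[seq_len(min(n_fields, length(x$fields)))]
  paste0(x$locus, "*", paste(sprintf("%02d", f), collapse = ":"))
}

#' @export
format.hla_allele <- function(x, ...) format_allele_name(x)

#' @export
print.hla_allele <- function(x, ...) {
  cat("<hla_allele> ", format_allele_name(x), "\n", sep = "")
  invisible(x)
}

#' Canonical two-field (protein-level) allele key
#'
#' Serotype assignment and all bead-level analytics operate at protein
#' resolution, so allele names are canonicalised to their first two fields.
#'
#' @param x Character vector of allele names (any accepted spelling).
#' @return Character vector of two-field canonical names, e.g.
#'   \code{"B*35:12"}.
#' @export
allele_key <- function(x) {
  vapply(x, function(s) format_allele_name(parse_allele_name(s), n_fields = 2L),
         character(1), USE.NAMES = FALSE)
}

#' Locus of an allele name
#'
#' @param x Character vector of allele names.
#' @return Character vector of loci.
#' @export
allele_locus <- function(x) {
  vapply(x, function(s) parse_allele_name(s)$locus, character(1),
         USE.NAMES = FALSE)
}
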
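# Residue tables hold one row per allele and one column per mature-protein
# position (header style: allele,pos103,pos109,...). Mature-protein
# coordinates are used throughout: position 1 is the first residue after the
# leader peptide. Cells are single upper-case amino-acid letters, "-" for an
# alignment gap, or NA when the residue is unknown (written as "?" on disk).

GAP <- "-"
UNKNOWN <- "?"

#' Build a residue table
#'
#' @param df A data.frame with an \code{allele} column and one \code{pos<N>}
#'   column per mature-protein position. Cells are amino-acid letters,
#'   \code{"-"} (gap), \code{"?"}/\code{NA} (unknown).
#' @return A \code{residue_table}: the validated data.frame with canonical
#'   two-field allele keys and an added \code{locus} column.
#' @export
residue_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"allele" %in% names(df))
    stop("residue table needs an 'allele' column", call. = FALSE)
  pos_cols <- grep("^pos[0-9]+$", names(df), value = TRUE)
  if (nrow(df) > 0 && length(pos_cols) == 0L)
    stop("residue table has no 'pos<N>' columns", call. = FALSE)
  out <- df[, c("allele", pos_cols), drop = FALSE]
  out$allele <- allele_key(out$allele)
  if (anyDuplicated(out$allele))
    stop("duplicate alleles in residue table: ",
         paste(unique(out$allele[duplicated(out$allele)]), collapse = ", "),
         call. = FALSE)
  for (p in pos_cols) {
    v <- toupper(trimws(as.character(out[[p]])))
    v[v %in% c("", UNKNOWN, "NA")] <- NA_character_
    bad <- !is.na(v) & !grepl("^[A-Z-]$", v)
    if (any(bad))
      stop(sprintf("invalid residue value(s) in %s: %s", p,
                   paste(unique(v[bad]), collapse = ", ")), call. = FALSE)
    out[[p]] <- v
  }
  out$locus <- allele_locus(out$allele)
  rownames(out) <- NULL
  class(out) <- c("residue_table", "data.frame")
  out
}

#' Read a residue table
#'
#' Two source dialects are supported. The flat CSV
#' (\code{allele,pos103,pos109,...}) is the canonical interchange format.
#' An IMGT-style \code{_prot} alignment can also be read: the first sequence
#' in the file is the reference, \code{"-"} means identity with the
#' reference, \code{"*"} and \code{"X"} mean unknown, and columns where the
#' reference itself carries \code{"."} are insertion columns, which are
#' skipped with a warning. \code{leader_offset} gives the number of leader
#' (signal peptide) residues preceding mature position 1 in the alignment.
#'
#' @param path File to read.
#' @param format \code{"csv"} or \code{"imgt_prot"}.
#' @param leader_offset Leader length for \code{imgt_prot} input.
#' @param positions For \code{imgt_prot}: optional integer vector of mature
#'   positions to retain (default: all).
#' @return A \code{residue_table}.
#' @export
read_residue_table <- function(path, format = c("csv", "imgt_prot"),
                               leader_offset = 24L, positions = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    if (nrow(df) == 0L) {
      warning("empty residue table: ", path)
      return(residue_table(data.frame(allele = character(0),
                                      pos1 = character(0))))
    }
    return(residue_table(df))
  }
  read_imgt_prot(path, leader_offset = leader_offset, positions = positions)
}

# IMGT-style alignment reader (best effort). Sequence lines look like
#   B*07:02:01  MLVMA PRTVL ...
# possibly split over several blocks that are concatenated per allele.
read_imgt_prot <- function(path, leader_offset = 24L, positions = NULL) {
  lines <- readLines(path, warn = FALSE)
  seqs <- list()
  order_seen <- character(0)
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Z0-9]+\\*[0-9:]+[NLSCAQ]?)\\s+(.+)$", ln))[[1]]
    if (length(m) == 0L) next
    name <- m[2]
    chunk <- gsub("\\s", "", m[3])
    if (!grepl("^[A-Z.*-]+$", chunk)) next
    if (is.null(seqs[[name]])) order_seen <- c(order_seen, name)
    seqs[[name]] <- paste0(if (is.null(seqs[[name]])) "" else seqs[[name]], chunk)
  }
  if (length(seqs) == 0L)
    stop("no alignment rows found in ", path, call. = FALSE)
  ref_name <- order_seen[1L]
  ref <- strsplit(seqs[[ref_name]], "")[[1L]]
  n <- length(ref)
  ins <- ref == "."
  if (any(ins))
    warning(sprintf("skipping %d insertion column(s) in %s", sum(ins), path))
  keep <- which(!ins)
  mature_pos <- seq_along(keep) - as.integer(leader_offset)
  sel <- mature_pos >= 1L
  if (!is.null(positions)) sel <- sel & mature_pos %in% as.integer(positions)
  cols <- keep[sel]
  pos_ids <- mature_pos[sel]
  rows <- lapply(order_seen, function(nm) {
    s <- strsplit(seqs[[nm]], "")[[1L]]
    if (length(s) < n) s <- c(s, rep("*", n - length(s)))
    if (length(s) != n)
      stop(sprintf("inconsistent row length for %s in %s", nm, path), call. = FALSE)
    r <- s[cols]
    ident <- r == "-"
    r[ident] <- ref[cols][ident]
    r[r %in% c("*", "X", ".")] <- NA_character_
    r
  })
  mat <- do.call(rbind, rows)
  df <- data.frame(allele = order_seen, stringsAsFactors = FALSE)
  for (j in seq_along(pos_ids)) df[[paste0("pos", pos_ids[j])]] <- mat[, j]
  residue_table(df)
}

#' Write a residue table to CSV
#'
#' Inverse of \code{read_residue_table(format = "csv")}: unknown residues
#' are written as \code{"?"} so a round trip reproduces the table.
#'
#' @param tbl A \code{residue_table}.
#' @param path Output file.
#' @export
write_residue_table <- function(tbl, path) {
  stopifnot(inherits(tbl, "residue_table"))
  out <- tbl[, setdiff(names(tbl), "locus"), drop = FALSE]
  for (p in grep("^pos[0-9]+$", names(out), value = TRUE))
    out[[p]][is.na(out[[p]])] <- UNKNOWN
  utils::write.csv(as.data.frame(out), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Residue at a mature-protein position
#'
#' Total lookup: returns \code{"?"} for positions not stored (or stored as
#' unknown) rather than raising, so partial tables - such as those holding
#' only the positions printed in published reactivity tables - remain usable.
#'
#' @param tbl A \code{residue_table}.
#' @param allele Allele name (any accepted spelling).
#' @param position Integer position(s), mature-protein coordinates.
#' @return Character vector of single letters; \code{"-"} gap, \code{"?"}
#'   unknown.
#' @export
residue_at <- function(tbl, allele, position) {
  stopifnot(inherits(tbl, "residue_table"))
  key <- allele_key(allele)
  i <- match(key, tbl$allele)
  vapply(position, function(p) {
    if (is.na(i)) return(UNKNOWN)
    col <- paste0("pos", as.integer(p))
    if (!col %in% names(tbl)) return(UNKNOWN)
    v <- tbl[[col]][i]
    if (is.na(v)) UNKNOWN else v
  }, character(1))
}

#' Residue record for one allele
#'
#' @param tbl A \code{residue_table}.
#' @param allele Allele name.
#' @return An \code{allele_record}: list with \code{allele} (canonical key),
#'   \code{locus}, and \code{residues}, a named character vector keyed by
#'   position (NA = unknown).
#' @export
residue_record <- function(tbl, allele) {
  stopifnot(inherits(tbl, "residue_table"))
  key <- allele_key(allele)
  i <- match(key, tbl$allele)
  pos_cols <- grep("^pos[0-9]+$", names(tbl), value = TRUE)
  res <- if (is.na(i)) rep(NA_character_, length(pos_cols))
         else unlist(tbl[i, pos_cols], use.names = FALSE)
  names(res) <- sub("^pos", "", pos_cols)
  structure(list(allele = key, locus = allele_locus(key), residues = res),
            class = "allele_record")
}
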
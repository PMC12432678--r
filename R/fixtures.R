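# Packaged reactivity tables. These ship the published single-antigen-bead
# eluate panels, crossmatch results, antigen-proposal listing and subject
# genotypes as machine-readable CSV so every analysis stage is testable
# without external downloads. The `label` column of the S2 panel carries
# the published positive/negative annotation (which at one bead, B*15:20,
# differs from a plain MFI>1000 recall on the eluate column - the printed
# annotation is authoritative for that panel).

FIXTURE_FILES <- c(
  ae1_sab          = "table_ae1_sab.csv",
  s2_sab           = "table_s2_sab.csv",
  s1_sab           = "table_s1_sab.csv",
  fxm_167          = "table_fxm_167.csv",
  fxm_103          = "table_fxm_103.csv",
  proposals        = "table_proposals.csv",
  previous_antigens = "previous_antigens.csv",
  antigen_members  = "antigen_members.csv",
  genotypes        = "genotypes.csv")

#' Load a packaged fixture table
#'
#' @param name One of \code{"ae1_sab"} (A1-eluate SAB panel with 167
#'   residues), \code{"s2_sab"} (S2 eluate class-I panel with 103/109),
#'   \code{"s1_sab"} (S1 eluate panel with 69/82/83/103/109),
#'   \code{"fxm_167"}/\code{"fxm_103"} (T-cell crossmatches),
#'   \code{"proposals"} (new Associated Antigen listing),
#'   \code{"previous_antigens"} (prototype catalogue),
#'   \code{"antigen_members"} (member alleles with residues),
#'   \code{"genotypes"} (subject HLA genotypes, long format).
#' @return data.frame.
#' @export
load_fixture <- function(name) {
  if (!name %in% names(FIXTURE_FILES))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(FIXTURE_FILES), collapse = ", "), call. = FALSE)
  path <- system.file("extdata", FIXTURE_FILES[[name]], package = "depsero")
  fix_compartment(utils::read.csv(path, stringsAsFactors = FALSE))
}

# read.csv turns an all-"T" compartment column into logical TRUE
fix_compartment <- function(df) {
  if ("compartment" %in% names(df) && is.logical(df$compartment))
    df$compartment <- ifelse(df$compartment, "T", "B")
  df
}

#' Residue table embedded in a fixture panel
#'
#' Extracts the \code{pos<N>} residue columns of a packaged SAB panel into
#' a \code{residue_table}.
#'
#' @param name \code{"ae1_sab"}, \code{"s2_sab"} or \code{"s1_sab"}.
#' @return A \code{residue_table}.
#' @export
fixture_residues <- function(name) {
  df <- load_fixture(name)
  keep <- c("allele", grep("^pos[0-9]+$", names(df), value = TRUE))
  residue_table(df[, keep, drop = FALSE])
}

#' Labelled beads from a fixture panel
#'
#' @param name \code{"ae1_sab"}, \code{"s2_sab"} or \code{"s1_sab"}.
#' @param column MFI column to carry (\code{"untreated"}, \code{"ae1"},
#'   \code{"ae2"}, \code{"ae3"}).
#' @param labels \code{"printed"} uses the published POS/NEG (or highlight)
#'   annotation shipped with the fixture; \code{"cutoff"} recomputes labels
#'   as MFI > \code{cutoff} on \code{column}.
#' @param cutoff Cutoff for \code{labels = "cutoff"} (default 1000).
#' @return data.frame \code{allele}, \code{label}, \code{mfi}; beads with a
#'   missing MFI (or missing printed label) are dropped.
#' @export
fixture_beads <- function(name, column, labels = c("printed", "cutoff"),
                          cutoff = 1000) {
  labels <- match.arg(labels)
  df <- load_fixture(name)
  if (!column %in% names(df))
    stop("fixture '", name, "' has no MFI column '", column, "'", call. = FALSE)
  mfi <- suppressWarnings(as.numeric(df[[column]]))
  if (labels == "printed") {
    lab_col <- if ("label" %in% names(df)) "label" else "score"
    if (!lab_col %in% names(df))
      stop("fixture '", name, "' carries no printed labels", call. = FALSE)
    lab <- toupper(df[[lab_col]])
  } else {
    lab <- ifelse(mfi > cutoff, "POS", "NEG")
  }
  keep <- !is.na(mfi) & !is.na(lab) & lab %in% c("POS", "NEG")
  data.frame(allele = allele_key(df$allele[keep]), label = lab[keep],
             mfi = mfi[keep], stringsAsFactors = FALSE)
}

#' Subject genotype lookup
#'
#' @param subject_id Subject identifier in the genotype fixture (or a
#'   genotype data.frame passed via \code{genotypes}).
#' @param genotypes Optional data.frame (\code{subject_id}, \code{allele});
#'   default: the packaged fixture.
#' @return Character vector of the subject's alleles.
#' @export
subject_alleles <- function(subject_id, genotypes = NULL) {
  if (is.null(genotypes)) genotypes <- load_fixture("genotypes")
  alle <- genotypes$allele[genotypes$subject_id == subject_id]
  if (!length(alle)) stop("unknown subject: ", subject_id, call. = FALSE)
  alle
}
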
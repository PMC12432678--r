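# Combinatorial search for residue-level hypotheses explaining a serum's
# bead reactivity. A hypothesis is a conjunction of (position,
# equivalence-class) terms; a bead satisfies it iff its DEP class matches
# every term (an unknown residue never satisfies a term). The search space
# is restricted to classes observed among the POSITIVE beads: the question
# asked is "which residues present in the reactive proteins explain the
# pattern", not which absences do.

# Internal: class matrix (beads x positions) of equivalence-class ids.
bead_signatures <- function(beads, registry, tbl, positions) {
  loci <- allele_locus(beads$allele)
  grps <- vapply(loci, function(l) locus_group_of(registry, l), character(1))
  if (any(is.na(grps)))
    stop("bead locus not covered by registry: ",
         paste(unique(loci[is.na(grps)]), collapse = ", "), call. = FALSE)
  if (length(unique(grps)) != 1L)
    stop("beads span more than one locus group: ",
         paste(unique(grps), collapse = ", "), call. = FALSE)
  grp <- grps[1L]
  positions <- as.character(positions)
  bad <- setdiff(positions, registry_positions(registry, grp))
  if (length(bad))
    stop("position(s) not registered for ", grp, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  sig <- t(vapply(beads$allele,
                  function(a) dep_signature(registry, tbl, a)[positions],
                  character(length(positions))))
  if (length(positions) == 1L) {
    sig <- matrix(sig, ncol = 1L)
  }
  colnames(sig) <- positions
  rownames(sig) <- NULL
  sig
}

term_string <- function(pos, cls) paste(paste0(pos, "=", cls), collapse = " & ")

#' Enumerate epitope hypotheses over labelled beads
#'
#' Builds every conjunction of up to \code{k_max} (position, class) terms
#' whose classes are observed among the positive beads, and counts how many
#' positive and negative beads each conjunction covers.
#'
#' @param beads data.frame with columns \code{allele}, \code{label}
#'   (\code{"POS"}/\code{"NEG"}) and optionally \code{mfi}.
#' @param registry A \code{dep_registry}.
#' @param tbl A \code{residue_table} resolving the bead alleles.
#' @param positions Character/integer vector of registry position ids to
#'   search over (e.g. \code{c("103", "109")}; the paired motif is
#'   \code{"82-83"}).
#' @param k_max Maximum number of terms per conjunction (default 2).
#' @return data.frame of hypotheses: \code{terms} (display string),
#'   \code{n_terms}, \code{covered_pos}, \code{covered_neg}, \code{n_pos},
#'   \code{n_neg}, plus list-columns \code{term_pos}, \code{term_class}.
#' @export
enumerate_hypotheses <- function(beads, registry, tbl, positions, k_max = 2L) {
  stopifnot(is.data.frame(beads), all(c("allele", "label") %in% names(beads)),
            k_max >= 1L)
  lab <- toupper(as.character(beads$label))
  if (!all(lab %in% c("POS", "NEG")))
    stop("bead labels must be POS or NEG", call. = FALSE)
  n_pos <- sum(lab == "POS"); n_neg <- sum(lab == "NEG")
  if (n_pos == 0L) stop("no positive beads: nothing to explain", call. = FALSE)
  if (n_neg == 0L) stop("no negative beads: nothing to separate from", call. = FALSE)
  sig <- bead_signatures(beads, registry, tbl, positions)
  positions <- colnames(sig)
  observed <- lapply(positions, function(p) {
    cls <- unique(sig[lab == "POS", p])
    cls[!is.na(cls)]
  })
  names(observed) <- positions
  usable <- positions[vapply(observed, length, integer(1)) > 0L]
  rows <- list()
  for (k in seq_len(min(k_max, length(usable)))) {
    for (combo in combn_list(usable, k)) {
      grid <- expand.grid(observed[combo], stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
      for (r in seq_len(nrow(grid))) {
        cls <- as.character(unlist(grid[r, , drop = TRUE]))
        sat <- rep(TRUE, nrow(sig))
        for (j in seq_along(combo)) {
          v <- sig[, combo[j]]
          sat <- sat & !is.na(v) & v == cls[j]
        }
        rows[[length(rows) + 1L]] <- list(
          terms = term_string(combo, cls), n_terms = k,
          covered_pos = sum(sat & lab == "POS"),
          covered_neg = sum(sat & lab == "NEG"),
          term_pos = combo, term_class = cls)
      }
    }
  }
  out <- data.frame(
    terms = vapply(rows, `[[`, character(1), "terms"),
    n_terms = vapply(rows, `[[`, integer(1), "n_terms"),
    covered_pos = vapply(rows, `[[`, integer(1), "covered_pos"),
    covered_neg = vapply(rows, `[[`, integer(1), "covered_neg"),
    n_pos = n_pos, n_neg = n_neg, stringsAsFactors = FALSE)
  out$term_pos <- lapply(rows, `[[`, "term_pos")
  out$term_class <- lapply(rows, `[[`, "term_class")
  out
}

combn_list <- function(x, k) {
  if (k > length(x)) return(list())
  m <- utils::combn(x, k)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

#' Rank epitope hypotheses
#'
#' Deterministic ordering: fewest covered negatives first, then most
#' covered positives, then fewest terms, then the term string
#' lexicographically. Perfect separators (all positives, no negatives)
#' therefore sort first.
#'
#' @param hypotheses data.frame from \code{enumerate_hypotheses}.
#' @return The same frame, reordered, with a \code{rank} column.
#' @export
rank_hypotheses <- function(hypotheses) {
  stopifnot(nrow(hypotheses) >= 1L)
  o <- order(hypotheses$covered_neg, -hypotheses$covered_pos,
             hypotheses$n_terms, hypotheses$terms)
  out <- hypotheses[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Flag hypotheses satisfied by self HLA proteins
#'
#' A hypothesis is a self-epitope candidate when at least one of the
#' subject's own alleles carries every term: antibodies against it are not
#' expected because of self-tolerance, so a reactivity pattern explained
#' only by a self-flagged hypothesis warrants scrutiny.
#'
#' @param hypotheses data.frame from \code{enumerate_hypotheses}.
#' @param registry A \code{dep_registry}.
#' @param tbl A \code{residue_table} resolving the self alleles (alleles
#'   absent from the table cannot satisfy any term).
#' @param self_alleles Character vector of the subject's alleles (may be
#'   empty: everything is then flagged non-self).
#' @param loci Optional restriction of which self loci to consider.
#' @return \code{hypotheses} with a logical \code{is_self} column.
#' @export
filter_self <- function(hypotheses, registry, tbl, self_alleles, loci = NULL) {
  self_alleles <- unique(self_alleles)
  if (!is.null(loci))
    self_alleles <- self_alleles[allele_locus(self_alleles) %in% loci]
  self_alleles <- self_alleles[allele_key(self_alleles) %in% tbl$allele]
  self_sigs <- list()
  for (a in self_alleles) {
    g <- locus_group_of(registry, allele_locus(a))
    if (!is.na(g)) self_sigs[[a]] <- dep_signature(registry, tbl, a)
  }
  hypotheses$is_self <- vapply(seq_len(nrow(hypotheses)), function(i) {
    pos <- hypotheses$term_pos[[i]]; cls <- hypotheses$term_class[[i]]
    any(vapply(self_sigs, function(sig) {
      all(pos %in% names(sig)) && all(!is.na(sig[pos]) & sig[pos] == cls)
    }, logical(1)))
  }, logical(1))
  hypotheses
}

#' Greedy multi-epitope decomposition
#'
#' Explains a serum's positive beads by iteratively selecting the
#' best-ranked hypothesis (per \code{rank_hypotheses}) among those covering
#' at least one still-uncovered positive bead - clean separators
#' (\code{covered_neg == 0}) are preferred automatically because the rank
#' order puts them first - removing the positives it covers, and repeating
#' until all positives are covered or \code{max_hypotheses} is reached.
#'
#' @inheritParams enumerate_hypotheses
#' @param max_hypotheses Stop after this many selections (default 10).
#' @return data.frame of the selected hypotheses in selection order, with
#'   \code{n_new_pos} (positives newly covered at selection time); the
#'   number of positives left uncovered is attached as
#'   \code{attr(, "uncovered_pos")}.
#' @export
greedy_cover <- function(beads, registry, tbl, positions, k_max = 2L,
                         max_hypotheses = 10L) {
  hyp <- enumerate_hypotheses(beads, registry, tbl, positions, k_max)
  hyp <- rank_hypotheses(hyp)
  lab <- toupper(as.character(beads$label))
  sig <- bead_signatures(beads, registry, tbl, positions)
  satisfies <- function(i) {
    pos <- hyp$term_pos[[i]]; cls <- hyp$term_class[[i]]
    sat <- rep(TRUE, nrow(sig))
    for (j in seq_along(pos)) {
      v <- sig[, pos[j]]
      sat <- sat & !is.na(v) & v == cls[j]
    }
    sat
  }
  uncovered <- which(lab == "POS")
  picked <- integer(0); n_new <- integer(0)
  while (length(uncovered) > 0L && length(picked) < max_hypotheses) {
    found <- FALSE
    for (i in seq_len(nrow(hyp))) {
      if (i %in% picked) next
      sat <- satisfies(i)
      new_pos <- intersect(which(sat), uncovered)
      if (length(new_pos) > 0L) {
        picked <- c(picked, i)
        n_new <- c(n_new, length(new_pos))
        uncovered <- setdiff(uncovered, new_pos)
        found <- TRUE
        break
      }
    }
    if (!found) break
  }
  out <- hyp[picked, , drop = FALSE]
  out$n_new_pos <- n_new
  rownames(out) <- NULL
  attr(out, "uncovered_pos") <- length(uncovered)
  out
}
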
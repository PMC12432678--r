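# Allele -> antigen assignment. An antigen is defined by its prototype
# allele's DEP signature; an allele is assigned to the antigen whose
# signature it matches. Categories:
#   FULL       exact class match at every registered position known on both
#              sides, nothing unknown where the antigen requires a class
#   SEROTYPE   mismatches confined to the registry's "pending" position set
#   INCOMPLETE matches where known, but required positions are unknown
#   UNASSIGNED no antigen matches

ASSIGN_CATEGORIES <- c("FULL", "SEROTYPE", "INCOMPLETE", "UNASSIGNED")

#' Build antigen definitions from a catalogue of prototype alleles
#'
#' @param catalogue data.frame with columns \code{antigen}, \code{prototype}
#'   and optionally \code{split}, \code{broad}.
#' @param registry A \code{dep_registry}.
#' @param tbl A \code{residue_table} resolving every prototype allele.
#' @return An \code{antigen_set}: the catalogue with \code{locus} and a
#'   \code{signature} list-column of prototype DEP signatures.
#' @export
antigen_set <- function(catalogue, registry, tbl) {
  stopifnot(is.data.frame(catalogue),
            all(c("antigen", "prototype") %in% names(catalogue)))
  missing <- setdiff(allele_key(catalogue$prototype), tbl$allele)
  if (length(missing))
    stop("prototype allele(s) absent from residue table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- catalogue
  out$prototype <- allele_key(out$prototype)
  out$locus <- allele_locus(out$prototype)
  if (!"split" %in% names(out)) out$split <- NA_character_
  if (!"broad" %in% names(out)) out$broad <- NA_character_
  out$signature <- lapply(out$prototype,
                          function(a) dep_signature(registry, tbl, a))
  class(out) <- c("antigen_set", "data.frame")
  out
}

match_against_antigen <- function(sig, asig, pending) {
  pos <- names(asig)
  required <- pos[!is.na(asig)]
  unknown <- required[is.na(sig[required])]
  known <- setdiff(required, unknown)
  mism <- known[sig[known] != asig[known]]
  mism_pending <- intersect(mism, pending)
  mism_hard <- setdiff(mism, pending)
  if (length(mism_hard)) return(NULL)
  if (length(mism_pending))
    list(category = "SEROTYPE", mismatched = mism_pending)
  else if (length(unknown))
    list(category = "INCOMPLETE", mismatched = unknown)
  else
    list(category = "FULL", mismatched = character(0))
}

#' Assign one allele to a serologic antigen
#'
#' @param registry A \code{dep_registry}.
#' @param tbl A \code{residue_table}.
#' @param allele Allele name.
#' @param antigens An \code{antigen_set} (see \code{\link{antigen_set}}).
#' @return A one-row data.frame: \code{allele}, \code{antigen},
#'   \code{category}, \code{mismatched_positions} (comma-joined; pending
#'   mismatches for SEROTYPE, unknown required positions for INCOMPLETE).
#' @export
assign_allele <- function(registry, tbl, allele, antigens) {
  stopifnot(inherits(antigens, "antigen_set"))
  key <- allele_key(allele)
  locus <- allele_locus(key)
  grp <- locus_group_of(registry, locus)
  pending <- if (!is.na(grp) && !is.null(registry$pending[[grp]]))
    registry$pending[[grp]] else character(0)
  sig <- dep_signature(registry, tbl, key)
  cand <- antigens[antigens$locus == locus, , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    m <- match_against_antigen(sig, cand$signature[[i]], pending)
    if (is.null(m)) next
    m$antigen <- cand$antigen[i]
    better <- is.null(best) ||
      match(m$category, ASSIGN_CATEGORIES) < match(best$category, ASSIGN_CATEGORIES) ||
      (m$category == best$category &&
         length(m$mismatched) < length(best$mismatched)) ||
      (m$category == best$category &&
         length(m$mismatched) == length(best$mismatched) &&
         m$antigen < best$antigen)
    if (better) best <- m
  }
  if (is.null(best))
    best <- list(antigen = NA_character_, category = "UNASSIGNED",
                 mismatched = character(0))
  data.frame(allele = key, antigen = best$antigen, category = best$category,
             mismatched_positions = paste(best$mismatched, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Assign every allele of a residue table
#'
#' @inheritParams assign_allele
#' @param alleles Optional character vector restricting which alleles to
#'   assign (default: all alleles of \code{tbl} whose locus the registry
#'   covers).
#' @return data.frame with one row per allele (see \code{assign_allele}).
#' @export
assign_alleles <- function(registry, tbl, antigens, alleles = NULL) {
  if (is.null(alleles)) {
    covered <- !is.na(vapply(tbl$locus, function(l) locus_group_of(registry, l),
                             character(1)))
    alleles <- tbl$allele[covered]
  }
  do.call(rbind, lapply(alleles, function(a)
    assign_allele(registry, tbl, a, antigens)))
}

#' Tabulate assignment categories per locus
#'
#' @param assignments data.frame from \code{assign_alleles}.
#' @return data.frame with columns \code{locus}, \code{FULL},
#'   \code{SEROTYPE}, \code{INCOMPLETE}, \code{UNASSIGNED}, \code{total};
#'   all-zero single-row frame for empty input.
#' @export
summarize_catalogue <- function(assignments) {
  if (is.null(assignments) || nrow(assignments) == 0L) {
    out <- data.frame(locus = character(0))
    for (cat in ASSIGN_CATEGORIES) out[[cat]] <- integer(0)
    out$total <- integer(0)
    return(out)
  }
  loci <- allele_locus(assignments$allele)
  out <- do.call(rbind, lapply(sort(unique(loci)), function(l) {
    sub <- assignments$category[loci == l]
    row <- data.frame(locus = l, stringsAsFactors = FALSE)
    for (cat in ASSIGN_CATEGORIES) row[[cat]] <- sum(sub == cat)
    row$total <- length(sub)
    row
  }))
  rownames(out) <- NULL
  out
}

# Associated Antigen naming: class I antigens take the locus, a hyphen and
# the four digits of the two-field prototype (B*55:04 -> B-5504). DP
# antigens follow the legacy DP convention: first field only when the
# protein is the :01 member (DPB1*15:01 -> DP-15), both fields otherwise.
propose_name <- function(allele) {
  a <- parse_allele_name(allele)
  f <- sprintf("%02d", a$fields[1:2])
  if (a$locus == "DPB1") {
    if (a$fields[2] == 1L) paste0("DP-", f[1]) else paste0("DP-", f[1], f[2])
  } else {
    paste0(a$locus, "-", f[1], f[2])
  }
}

#' Propose new Associated Antigens after adding DEP positions
#'
#' When a registry update adds one or more DEP positions, every existing
#' antigen whose member alleles fall into more than one equivalence class at
#' the new positions is split: the class containing the previous prototype
#' keeps the antigen name, and each other class becomes a proposed antigen
#' named after its lowest-numbered member allele (hyphenated prototype
#' convention). Proposals inherit the previous antigen's WHO split/broad
#' roots.
#'
#' @param registry_before,registry_after Registries before and after the
#'   update; \code{registry_after} must add at least one position.
#' @param tbl A \code{residue_table} covering all member alleles at the new
#'   positions.
#' @param catalogue data.frame of previous antigens (\code{antigen},
#'   \code{prototype}, optional \code{split}, \code{broad}).
#' @param membership Optional data.frame (\code{allele}, \code{antigen})
#'   stating which alleles belonged to each previous antigen. When omitted,
#'   membership is computed by assigning every allele of \code{tbl} under
#'   \code{registry_before}.
#' @param loci Optional character vector restricting the loci considered.
#' @return data.frame of proposals: \code{locus}, \code{proposed},
#'   \code{dep1}, \code{previous}, \code{dep2}, \code{split}, \code{broad},
#'   \code{splitting_positions}, \code{n_members}; sorted by locus, previous
#'   antigen, proposed name.
#' @export
propose_new_antigens <- function(registry_before, registry_after, tbl,
                                 catalogue, membership = NULL, loci = NULL) {
  stopifnot(is.data.frame(catalogue),
            all(c("antigen", "prototype") %in% names(catalogue)))
  cat_df <- catalogue
  cat_df$prototype <- allele_key(cat_df$prototype)
  cat_df$locus <- allele_locus(cat_df$prototype)
  if (!"split" %in% names(cat_df)) cat_df$split <- NA_character_
  if (!"broad" %in% names(cat_df)) cat_df$broad <- NA_character_
  if (!is.null(loci)) cat_df <- cat_df[cat_df$locus %in% loci, , drop = FALSE]

  missing <- setdiff(cat_df$prototype, tbl$allele)
  if (length(missing))
    stop("prototype allele(s) missing from the residue data: ",
         paste(missing, collapse = ", "), call. = FALSE)

  if (is.null(membership)) {
    ants <- antigen_set(cat_df, registry_before, tbl)
    asg <- assign_alleles(registry_before, tbl, ants)
    asg <- asg[!is.na(asg$antigen) &
                 asg$category %in% c("FULL", "SEROTYPE", "INCOMPLETE"), ]
    membership <- asg[, c("allele", "antigen")]
  } else {
    stopifnot(all(c("allele", "antigen") %in% names(membership)))
    membership <- data.frame(allele = allele_key(membership$allele),
                             antigen = membership$antigen,
                             stringsAsFactors = FALSE)
  }

  proposals <- list()
  for (i in seq_len(nrow(cat_df))) {
    ant <- cat_df$antigen[i]
    proto <- cat_df$prototype[i]
    grp <- locus_group_of(registry_after, cat_df$locus[i])
    if (is.na(grp)) next
    new_pos <- setdiff(registry_positions(registry_after, grp),
                       registry_positions(registry_before, grp))
    if (!length(new_pos)) next
    members <- unique(c(proto, membership$allele[membership$antigen == ant]))
    members <- members[allele_locus(members) == cat_df$locus[i]]
    sigs <- lapply(members, function(a) dep_signature(registry_after, tbl, a)[new_pos])
    known <- vapply(sigs, function(s) !any(is.na(s)), logical(1))
    members <- members[known]; sigs <- sigs[known]
    if (!proto %in% members) next  # prototype unresolved at the new positions
    keys <- vapply(sigs, paste, character(1), collapse = "|")
    proto_key <- keys[match(proto, members)]
    for (k in setdiff(unique(keys), proto_key)) {
      cls_members <- members[keys == k]
      fields <- t(vapply(cls_members,
                         function(a) parse_allele_name(a)$fields[1:2],
                         integer(2)))
      namer <- cls_members[order(fields[, 1], fields[, 2])][1]
      sig_new <- sigs[[match(cls_members[1], members)]]
      sig_proto <- sigs[[match(proto, members)]]
      d <- new_pos[sig_new != sig_proto]
      proposals[[length(proposals) + 1L]] <- data.frame(
        locus = cat_df$locus[i],
        proposed = propose_name(namer),
        dep1 = paste0(d, sig_new[d], collapse = "+"),
        previous = ant,
        dep2 = paste0(d, sig_proto[d], collapse = "+"),
        split = cat_df$split[i],
        broad = cat_df$broad[i],
        splitting_positions = paste(d, collapse = ","),
        n_members = length(cls_members),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(proposals)) {
    return(data.frame(locus = character(0), proposed = character(0),
                      dep1 = character(0), previous = character(0),
                      dep2 = character(0), split = character(0),
                      broad = character(0), splitting_positions = character(0),
                      n_members = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, proposals)
  out <- out[order(out$locus, out$previous, out$proposed), ]
  rownames(out) <- NULL
  out
}
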
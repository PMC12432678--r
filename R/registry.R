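# The DEP registry declares, per locus group, which mature-protein positions
# determine serologic epitopes and which residues at each position behave as
# serologically equivalent. A position's "classes" partition the residues
# seen there; residues not listed fall into an implicit singleton class.
# A position may span two adjacent sites (a paired motif such as 82-83,
# where the LR combination marks Bw4); its residue value is the
# concatenation of the site residues.

#' Load a DEP registry from a YAML config
#'
#' The shipped default registry covers HLA class I (A/B/C), HLA-DPB1 and
#' HLA-DRB1/3/4/5. Explicit classes in the default: class I 103 \{L\}/\{V\}/\{M\},
#' 109 \{F\}/\{L\}, 167 \{G,S\}/\{W\}, the 82-83 paired motif \{LR\} vs other;
#' DPB1 96 \{R\}/\{K\} and 69 \{R,K\} (single class, i.e. not distinguishing);
#' DRB 71 \{R,K\}.
#'
#' @param path YAML config; \code{NULL} loads the shipped default.
#' @return A \code{dep_registry}.
#' @export
load_registry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_registry.yaml", package = "depsero")
  if (!file.exists(path)) stop("registry config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$locus_groups)) stop("registry config lacks 'locus_groups'", call. = FALSE)
  groups <- lapply(cfg$locus_groups, function(g) {
    positions <- list()
    for (p in g$positions) {
      id <- as.character(p$id)
      sites <- if (!is.null(p$sites)) as.integer(unlist(p$sites)) else
        as.integer(id)
      classes <- lapply(p$classes, function(cl) toupper(as.character(unlist(cl))))
      all_res <- unlist(classes)
      if (anyDuplicated(all_res))
        stop(sprintf("position %s: residue(s) %s appear in more than one class",
                     id, paste(unique(all_res[duplicated(all_res)]), collapse = ", ")),
             call. = FALSE)
      positions[[id]] <- list(id = id, sites = sites, classes = classes)
    }
    list(loci = as.character(unlist(g$loci)),
         positions = positions,
         non_dep = as.integer(unlist(g$non_dep)))
  })
  pending <- lapply(cfg$pending, function(p) as.character(unlist(p)))
  structure(list(groups = groups, pending = pending), class = "dep_registry")
}

#' The shipped default DEP registry
#' @return A \code{dep_registry}.
#' @export
default_registry <- function() load_registry(NULL)

#' @export
print.dep_registry <- function(x, ...) {
  cat("<dep_registry>\n")
  for (g in names(x$groups)) {
    gp <- x$groups[[g]]
    cat(sprintf("  %s (%s): positions %s\n", g,
                paste(gp$loci, collapse = "/"),
                paste(names(gp$positions), collapse = ", ")))
  }
  invisible(x)
}

#' Locus group containing a locus
#' @param registry A \code{dep_registry}.
#' @param locus Locus name, e.g. \code{"B"}.
#' @return Group name, or \code{NA} if the locus is not covered.
#' @export
locus_group_of <- function(registry, locus) {
  for (g in names(registry$groups))
    if (locus %in% registry$groups[[g]]$loci) return(g)
  NA_character_
}

#' Registered DEP position ids of a locus group
#' @param registry A \code{dep_registry}.
#' @param locus_group Group name, e.g. \code{"classI"}.
#' @return Character vector of position ids.
#' @export
registry_positions <- function(registry, locus_group) {
  grp <- registry$groups[[locus_group]]
  if (is.null(grp)) stop("unknown locus group: ", locus_group, call. = FALSE)
  names(grp$positions)
}

#' Drop DEP positions from a registry
#'
#' Used to reconstruct an earlier registry state, e.g. the one in force
#' before positions 103/109 (class I) or 96 (DPB1) were validated.
#'
#' @param registry A \code{dep_registry}.
#' @param locus_group Group to modify.
#' @param positions Character vector of position ids to remove.
#' @return The modified registry.
#' @export
registry_without_positions <- function(registry, locus_group, positions) {
  grp <- registry$groups[[locus_group]]
  if (is.null(grp)) stop("unknown locus group: ", locus_group, call. = FALSE)
  positions <- as.character(positions)
  missing <- setdiff(positions, names(grp$positions))
  if (length(missing))
    stop("position(s) not in registry: ", paste(missing, collapse = ", "),
         call. = FALSE)
  grp$positions <- grp$positions[setdiff(names(grp$positions), positions)]
  registry$groups[[locus_group]] <- grp
  registry
}

class_id <- function(members) paste(sort(members), collapse = "/")

#' Serological equivalence class of a residue
#'
#' @param registry A \code{dep_registry}.
#' @param locus_group Group name.
#' @param position Position id (character or integer).
#' @param residue Residue value at the position (for a paired motif, the
#'   concatenated site residues, e.g. \code{"LR"}).
#' @return The class id: explicit classes are named by their sorted members
#'   joined with \code{"/"} (\code{"G/S"}); an unlisted residue is its own
#'   implicit singleton class. \code{NA} residue yields \code{NA}.
#' @export
equivalence_class_of <- function(registry, locus_group, position, residue) {
  grp <- registry$groups[[locus_group]]
  if (is.null(grp)) stop("unknown locus group: ", locus_group, call. = FALSE)
  p <- grp$positions[[as.character(position)]]
  if (is.null(p))
    stop(sprintf("position %s is not registered for %s", position, locus_group),
         call. = FALSE)
  if (is.na(residue) || residue == "?") return(NA_character_)
  residue <- toupper(residue)
  for (cl in p$classes)
    if (residue %in% cl) return(class_id(cl))
  residue
}

#' DEP signature of an allele record
#'
#' One equivalence-class id per registered position of the allele's locus
#' group; \code{NA} where the underlying residue is unknown (a paired motif
#' is unknown if either site is). Explicit non-DEP positions never appear.
#'
#' @param registry A \code{dep_registry}.
#' @param record An \code{allele_record} (see \code{residue_record}).
#' @return Named character vector of class ids keyed by position id.
#' @export
signature_of_allele <- function(registry, record) {
  stopifnot(inherits(record, "allele_record"))
  g <- locus_group_of(registry, record$locus)
  if (is.na(g))
    stop("locus ", record$locus, " is not covered by the registry", call. = FALSE)
  grp <- registry$groups[[g]]
  sig <- vapply(grp$positions, function(p) {
    res <- record$residues[as.character(p$sites)]
    if (any(is.na(res)) || any(res == "?", na.rm = TRUE)) return(NA_character_)
    equivalence_class_of(registry, g, p$id, paste(res, collapse = ""))
  }, character(1))
  names(sig) <- names(grp$positions)
  sig
}

#' Convenience: DEP signature straight from a residue table
#' @param registry A \code{dep_registry}.
#' @param tbl A \code{residue_table}.
#' @param allele Allele name.
#' @return As \code{signature_of_allele}.
#' @export
dep_signature <- function(registry, tbl, allele) {
  signature_of_allele(registry, residue_record(tbl, allele))
}

#' Positions at which two DEP signatures differ
#'
#' Only positions whose class ids are known on both sides can distinguish;
#' unknowns never create a split. An empty result means the two signatures
#' are serologically equivalent as far as the available residues tell.
#'
#' @param registry A \code{dep_registry} (unused beyond validation; kept so
#'   the call site names the convention in force).
#' @param sig_a,sig_b Signatures from \code{signature_of_allele} over the
#'   same locus group.
#' @return Character vector of position ids (possibly empty).
#' @export
distinguishing_positions <- function(registry, sig_a, sig_b) {
  if (!identical(sort(names(sig_a)), sort(names(sig_b))))
    stop("signatures cover different position sets (different locus groups?)",
         call. = FALSE)
  pos <- names(sig_a)
  diff <- !is.na(sig_a) & !is.na(sig_b[pos]) & sig_a != sig_b[pos]
  pos[diff]
}
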
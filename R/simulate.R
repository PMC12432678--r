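# Synthetic residue tables and serum panels with planted structure.
#
# The MFI model is deliberately simple: a bead carrying the serum's epitope
# draws from a "positive" lognormal regime, any other bead from a
# "background" regime, and values are capped at a bead-saturation ceiling.
# Defaults emulate the regimes seen on clinical single-antigen-bead panels:
# background mostly 0-1000 with a small tail above the positivity cutoff,
# positives mostly 3000-35000. The generator plants known epitopes and
# known discordant sera so recovery can be verified against ground truth.

#' Simulation configuration
#'
#' @param seed Integer seed (mandatory; the generator is deterministic
#'   given the config).
#' @param n_alleles_per_locus Alleles per locus (default 20).
#' @param loci Loci to simulate (default A, B, C).
#' @param positions Named list: residue alphabet per position, e.g.
#'   \code{list("103" = c("L","V"), "109" = c("F","L"))}.
#' @param planted_epitopes List of epitopes; each epitope is a named list
#'   of position -> residue, e.g. \code{list("103"="V","109"="L")}. Sera
#'   are assigned epitopes round-robin.
#' @param epitope_prevalence Fraction of alleles carrying each planted
#'   epitope (at least 2 alleles, at most half the panel).
#' @param n_sera Number of sera (default 20).
#' @param background_meanlog,background_sdlog Background log-MFI regime
#'   (defaults log(150), 1.0: ~3\% of background beads exceed 1000).
#' @param positive_meanlog,positive_sdlog Positive log-MFI regime
#'   (defaults log(12000), 0.5).
#' @param mfi_cap Saturation ceiling (default 35000).
#' @param planted_discordant Optional data.frame (\code{allele_x},
#'   \code{allele_y}, \code{n}) of bead pairs for which \code{n} extra sera
#'   are injected reacting high on X (9000-20000) and negative on Y
#'   (< 500).
#' @return A validated \code{sim_config}.
#' @export
sim_config <- function(seed,
                       n_alleles_per_locus = 20L,
                       loci = c("A", "B", "C"),
                       positions = list("103" = c("L", "V"),
                                        "109" = c("F", "L"),
                                        "167" = c("G", "S", "W")),
                       planted_epitopes = list(list("103" = "V", "109" = "L")),
                       epitope_prevalence = 0.3,
                       n_sera = 20L,
                       background_meanlog = log(150),
                       background_sdlog = 1.0,
                       positive_meanlog = log(12000),
                       positive_sdlog = 0.5,
                       mfi_cap = 35000,
                       planted_discordant = NULL) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("seed is mandatory", call. = FALSE)
  if (n_alleles_per_locus < 1L)
    stop("n_alleles_per_locus must be at least 1", call. = FALSE)
  if (background_meanlog >= positive_meanlog)
    stop("background regime must sit below the positive regime", call. = FALSE)
  if (epitope_prevalence <= 0 || epitope_prevalence > 0.5)
    stop("epitope_prevalence must be in (0, 0.5]", call. = FALSE)
  for (ep in planted_epitopes) {
    bad <- setdiff(names(ep), names(positions))
    if (length(bad))
      stop("planted epitope refers to unsimulated position(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 n_alleles_per_locus = as.integer(n_alleles_per_locus),
                 loci = loci, positions = positions,
                 planted_epitopes = planted_epitopes,
                 epitope_prevalence = epitope_prevalence,
                 n_sera = as.integer(n_sera),
                 background_meanlog = background_meanlog,
                 background_sdlog = background_sdlog,
                 positive_meanlog = positive_meanlog,
                 positive_sdlog = positive_sdlog,
                 mfi_cap = mfi_cap,
                 planted_discordant = planted_discordant),
            class = "sim_config")
}

carries_epitope <- function(tbl, allele, epitope) {
  all(vapply(names(epitope), function(p)
    identical(residue_at(tbl, allele, as.integer(p)), toupper(epitope[[p]])),
    logical(1)))
}

#' Generate a synthetic residue table
#'
#' Residues are drawn uniformly from each position's alphabet; each planted
#' epitope's residue combination is then forced onto a fixed-prevalence
#' carrier subset and cleared (one position mutated) from non-carriers, so
#' that between 2 alleles and half the panel carry it exactly.
#'
#' @param config A \code{sim_config}.
#' @return A \code{residue_table} with attribute \code{"carriers"}: a named
#'   list of carrier alleles per planted epitope.
#' @export
generate_allele_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  alleles <- unlist(lapply(config$loci, function(l)
    sprintf("%s*%02d:01", l, seq_len(config$n_alleles_per_locus))))
  n <- length(alleles)
  df <- data.frame(allele = alleles, stringsAsFactors = FALSE)
  for (p in names(config$positions))
    df[[paste0("pos", p)]] <- sample(config$positions[[p]], n, replace = TRUE)
  carriers <- list()
  for (e in seq_along(config$planted_epitopes)) {
    ep <- config$planted_epitopes[[e]]
    n_carry <- max(2L, round(config$epitope_prevalence * n))
    n_carry <- min(n_carry, floor(n / 2))
    if (n_carry < 2L)
      stop("panel too small to plant an epitope in at least 2 alleles",
           call. = FALSE)
    idx <- sample.int(n, n_carry)
    for (p in names(ep)) df[[paste0("pos", p)]][idx] <- toupper(ep[[p]])
    # non-carriers must differ at >= 1 epitope position
    for (i in setdiff(seq_len(n), idx)) {
      matches <- vapply(names(ep), function(p)
        df[[paste0("pos", p)]][i] == toupper(ep[[p]]), logical(1))
      if (all(matches)) {
        p <- names(ep)[1L]
        alt <- setdiff(config$positions[[p]], toupper(ep[[p]]))
        if (!length(alt))
          stop("position ", p, " has a single-letter alphabet; cannot clear ",
               "the planted epitope from non-carriers", call. = FALSE)
        df[[paste0("pos", p)]][i] <- sample(alt, 1L)
      }
    }
    carriers[[e]] <- alleles[sort(idx)]
  }
  tbl <- residue_table(df)
  attr(tbl, "carriers") <- carriers
  tbl
}

#' Generate a synthetic serum panel with ground truth
#'
#' Each serum is assigned one planted epitope (round-robin; with no planted
#' epitopes all sera are pure background). Beads carrying the serum's
#' epitope draw from the positive lognormal regime, all other beads from
#' the background regime; everything is capped at \code{mfi_cap}. Planted
#' discordant sera are appended afterwards. Ground truth is returned as a
#' sidecar object, never inside the panel itself.
#'
#' @param config A \code{sim_config}.
#' @param tbl Residue table from \code{generate_allele_table(config)}.
#' @return list with \code{panel} (a \code{serum_panel}) and \code{truth}
#'   (list: \code{serum_epitopes}, \code{carriers}, \code{discordant}).
#' @export
generate_serum_panel <- function(config, tbl) {
  stopifnot(inherits(config, "sim_config"), inherits(tbl, "residue_table"))
  set.seed(config$seed + 1L)
  alleles <- tbl$allele
  n_ep <- length(config$planted_epitopes)
  serum_ids <- sprintf("SYN%03d", seq_len(config$n_sera))
  serum_ep <- if (n_ep > 0) ((seq_len(config$n_sera) - 1L) %% n_ep) + 1L
              else rep(NA_integer_, config$n_sera)
  draw <- function(n, positive) {
    m <- if (positive) config$positive_meanlog else config$background_meanlog
    s <- if (positive) config$positive_sdlog else config$background_sdlog
    pmin(round(stats::rlnorm(n, m, s)), config$mfi_cap)
  }
  rows <- vector("list", config$n_sera)
  for (i in seq_len(config$n_sera)) {
    hot <- if (is.na(serum_ep[i])) rep(FALSE, length(alleles)) else {
      ep <- config$planted_epitopes[[serum_ep[i]]]
      vapply(alleles, carries_epitope, logical(1), tbl = tbl, epitope = ep,
             USE.NAMES = FALSE)
    }
    mfi <- numeric(length(alleles))
    mfi[hot] <- draw(sum(hot), TRUE)
    mfi[!hot] <- draw(sum(!hot), FALSE)
    rows[[i]] <- data.frame(serum_id = serum_ids[i], allele = alleles,
                            mfi = mfi, stringsAsFactors = FALSE)
  }
  disc_truth <- NULL
  if (!is.null(config$planted_discordant)) {
    pd <- config$planted_discordant
    if (!"n" %in% names(pd)) pd$n <- 1L
    cnt <- 0L
    for (i in seq_len(nrow(pd))) {
      for (j in seq_len(pd$n[i])) {
        cnt <- cnt + 1L
        sid <- sprintf("DIS%03d", cnt)
        mfi <- pmin(round(stats::rlnorm(length(alleles),
                                        config$background_meanlog,
                                        config$background_sdlog)),
                    config$mfi_cap)
        names(mfi) <- alleles
        mfi[allele_key(pd$allele_x[i])] <- round(stats::runif(1, 9000, 20000))
        mfi[allele_key(pd$allele_y[i])] <- round(stats::runif(1, 0, 500))
        rows[[length(rows) + 1L]] <- data.frame(serum_id = sid,
                                                allele = alleles,
                                                mfi = unname(mfi),
                                                stringsAsFactors = FALSE)
        disc_truth <- rbind(disc_truth,
                            data.frame(serum_id = sid,
                                       allele_x = allele_key(pd$allele_x[i]),
                                       allele_y = allele_key(pd$allele_y[i]),
                                       stringsAsFactors = FALSE))
      }
    }
  }
  panel <- serum_panel(do.call(rbind, rows))
  truth <- list(
    serum_epitopes = stats::setNames(as.list(serum_ep), serum_ids),
    carriers = attr(tbl, "carriers"),
    discordant = disc_truth)
  list(panel = panel, truth = truth)
}
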
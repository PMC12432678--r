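# Independent oracles used to cross-check the package's computations.
# They deliberately avoid the code paths they validate.

# Closed-form ordinary least squares via the normal equations.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  yhat <- as.vector(X %*% beta)
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], r_squared = r2)
}

# Exhaustive search for the best residue conjunction, working directly on
# raw residue letters (valid when every registry class is an implicit
# singleton). Ordering mirrors the documented ranking contract.
brute_force_hypotheses <- function(beads, res_df, positions, k_max) {
  lab <- toupper(beads$label)
  letter <- function(allele, p) {
    v <- res_df[[paste0("pos", p)]][match(allele, res_df$allele)]
    ifelse(is.na(v), NA_character_, v)
  }
  pos_letters <- lapply(positions, function(p) {
    l <- unique(letter(beads$allele[lab == "POS"], p))
    l[!is.na(l)]
  })
  names(pos_letters) <- positions
  rows <- list()
  for (k in seq_len(k_max)) {
    if (k > length(positions)) break
    combos <- utils::combn(positions, k, simplify = FALSE)
    for (combo in combos) {
      grid <- expand.grid(pos_letters[combo], stringsAsFactors = FALSE)
      for (r in seq_len(nrow(grid))) {
        cls <- as.character(unlist(grid[r, , drop = TRUE]))
        sat <- rep(TRUE, nrow(beads))
        for (j in seq_along(combo)) {
          v <- letter(beads$allele, combo[j])
          sat <- sat & !is.na(v) & v == cls[j]
        }
        rows[[length(rows) + 1L]] <- data.frame(
          terms = paste(paste0(combo, "=", cls), collapse = " & "),
          n_terms = k,
          covered_pos = sum(sat & lab == "POS"),
          covered_neg = sum(sat & lab == "NEG"),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$covered_neg, -out$covered_pos, out$n_terms, out$terms), ]
}

# Random residue table + labels over singleton-class positions, for oracle
# equivalence checks.
random_bead_problem <- function(seed, n_beads = 20, positions = c(1, 2, 3, 4)) {
  set.seed(seed)
  df <- data.frame(allele = sprintf("B*%02d:01", seq_len(n_beads)),
                   stringsAsFactors = FALSE)
  for (p in positions)
    df[[paste0("pos", p)]] <- sample(c("A", "G", "S"), n_beads, replace = TRUE)
  lab <- sample(c("POS", "NEG"), n_beads, replace = TRUE)
  while (!any(lab == "POS") || !any(lab == "NEG"))
    lab <- sample(c("POS", "NEG"), n_beads, replace = TRUE)
  list(res = df,
       beads = data.frame(allele = df$allele, label = lab,
                          stringsAsFactors = FALSE))
}

# Minimal registry file whose positions all use implicit singleton classes.
write_singleton_registry <- function(positions, path = tempfile(fileext = ".yaml")) {
  lines <- c("locus_groups:", "  classI:", "    loci: [A, B, C]",
             "    positions:")
  for (p in positions) lines <- c(lines, sprintf('      - id: "%s"', p))
  writeLines(lines, path)
  path
}
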
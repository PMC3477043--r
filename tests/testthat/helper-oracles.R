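# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately use different code paths from the package
# implementation (double loops, brute-force scans, svd instead of eigen).

# Eq.-style variance-covariance by explicit double loop, (M-1) denominator
bruteforce_cov <- function(X) {
  M <- nrow(X)
  N <- ncol(X)
  abar <- colSums(X) / M
  C <- matrix(0, N, N)
  for (k in seq_len(N)) {
    for (l in seq_len(N)) {
      s <- 0
      for (i in seq_len(M)) {
        s <- s + (X[i, k] - abar[k]) * (X[i, l] - abar[l])
      }
      C[k, l] <- s / (M - 1)
    }
  }
  C
}

# brute-force contact extraction: all-pairs distance scan over data frames
bruteforce_contacts <- function(model, lig_resname, cutoff) {
  a <- model$atoms
  lig <- a[a$resid == lig_resname & !(toupper(a$elesy) %in% c("H", "D")), ]
  cand <- a[a$resid != lig_resname & !(toupper(a$elesy) %in% c("H", "D")), ]
  hits <- c()
  for (i in seq_len(nrow(cand))) {
    for (j in seq_len(nrow(lig))) {
      d <- sqrt((cand$x[i] - lig$x[j])^2 + (cand$y[i] - lig$y[j])^2 +
                  (cand$z[i] - lig$z[j])^2)
      if (d <= cutoff) hits <- c(hits, cand$resno[i])
    }
  }
  sort(unique(hits))
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_res <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

write_toy_fasta <- function(seqs, ids = names(seqs)) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

write_toy_clustal <- function(seqs, ids = names(seqs)) {
  path <- withr::local_tempfile(fileext = ".aln",
                                .local_envir = parent.frame())
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "", "",
               sprintf("%-12s%s", ids, seqs), ""), path)
  path
}

# random equal-length residue strings over the 20 amino acids
random_strings <- function(n, P, seed) {
  set.seed(seed)
  ab <- pocketpca::aa_alphabet()[1:20]
  vapply(seq_len(n), function(i) {
    paste0(sample(ab, P, replace = TRUE), collapse = "")
  }, character(1))
}

# the two-mode synthetic spec mimicking the 23/26 and 277 axes
tubulin_like_spec <- function(n = 200, noise = 0, seed = 1) {
  synthetic_alignment_spec(
    n, "EVDDHASFTSRRGL",
    modes = list(
      list(positions = c(2L, 3L), letters = c("T", "G"), prob = 0.5),
      list(positions = 10L, letters = "A", prob = 0.5)
    ),
    noise = noise, seed = seed
  )
}

synthetic_mode_features <- function() {
  list(pc1 = list(list(column = 2L, letters = "T")),
       pc2 = list(list(column = 10L, letters = "S")))
}

synthetic_truth_groups <- function(modes) {
  ifelse(modes[, 1], ifelse(modes[, 2], "B", "A"),
         ifelse(modes[, 2], "D", "C"))
}
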
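# Shared fixtures and independent oracles used across test files.

# A small three-generation pedigree built by hand: grandparents, their two
# children married to unrelated spouses, and grandchildren (one inbred-free
# cousin pair). Used to exercise the tabular method beyond nuclear families.
three_generation_pedigree <- function() {
  data.frame(
    individual_id = c("gp1", "gm1", "sp1", "sp2", "c1", "c2",
                      "g1", "g2", "g3"),
    family_id = "F1",
    father_id = c(NA, NA, NA, NA, "gp1", "gp1", "c1", "c1", "c2"),
    mother_id = c(NA, NA, NA, NA, "gm1", "gm1", "sp1", "sp1", "sp2"),
    sex = c("male", "female", "female", "female", "male", "male",
            "male", "female", "male"),
    age = c(70, 70, 45, 45, 45, 45, 15, 15, 15),
    zygosity = "none",
    twin_pair = NA_character_,
    stringsAsFactors = FALSE
  )
}

# Gene-dropping estimate of the additive relationship 2*P(alleles IBD):
# founders get unique allele labels, children inherit one random allele per
# parent; the kinship coefficient is the probability that randomly drawn
# alleles from i and j descend from the same founder copy.
gene_drop_relationship <- function(ped, reps = 50000, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  ord <- methfam:::pedigree_order(ped)
  fi <- match(ped$father_id, ped$individual_id)
  mi <- match(ped$mother_id, ped$individual_id)
  # allele labels per replicate: reps x n matrices for each chromosome copy
  a1 <- matrix(0L, reps, n)
  a2 <- matrix(0L, reps, n)
  lab <- 0L
  for (i in ord) {
    if (is.na(fi[i])) {
      a1[, i] <- lab + 1L
      a2[, i] <- lab + 2L
      lab <- lab + 2L
    } else {
      pick <- stats::runif(reps) < 0.5
      a1[, i] <- ifelse(pick, a1[, fi[i]], a2[, fi[i]])
      pick <- stats::runif(reps) < 0.5
      a2[, i] <- ifelse(pick, a1[, mi[i]], a2[, mi[i]])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ped$individual_id, ped$individual_id))
  for (i in seq_len(n)) for (j in i:n) {
    phi <- (rowMeans(cbind(a1[, i] == a1[, j], a1[, i] == a2[, j],
                           a2[, i] == a1[, j], a2[, i] == a2[, j])))
    A[i, j] <- A[j, i] <- 2 * mean(phi)
  }
  A
}

# Dense multivariate-normal log-likelihood of the AE model, written with
# generic solve()/determinant() so it is independent of the package's
# rotated-likelihood code path. Mean is profiled by GLS.
dense_ae_loglik <- function(y, A, va, ve) {
  n <- length(y)
  S <- va * A + ve * diag(n)
  Si <- solve(S)
  one <- rep(1, n)
  beta <- sum(Si %*% y) / sum(Si %*% one)
  r <- y - beta
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + ld + drop(t(r) %*% Si %*% r))
}

# One-way ANOVA mean squares via stats::aov, an independent route to the
# intraclass correlation.
aov_icc <- function(a, b) {
  df <- data.frame(value = c(a, b),
                   pair = factor(rep(seq_along(a), 2)))
  ms <- summary(stats::aov(value ~ pair, df))[[1]][["Mean Sq"]]
  (ms[1] - ms[2]) / (ms[1] + ms[2])
}

# Standard 117-family cohort reused by several acceptance checks.
study_pedigree <- function(seed = 1) generate_pedigree(117, seed = seed)
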
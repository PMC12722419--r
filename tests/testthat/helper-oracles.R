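# Independent oracles used to check the implementation paths.  Everything
# here is written from first principles (enumeration, closed forms, direct
# risk-set arithmetic) and never calls the package functions it validates.

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables with the same margins whose point
# probability does not exceed the observed one.
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n_ <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n_):min(k, m)
  probs <- dhyper(support, m, n_, k)
  p_obs <- dhyper(tab[1, 1], m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Log-rank chi-square statistic for two groups by direct risk-set
# accumulation at each distinct event time.
oracle_logrank_chisq <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(max(g) == 2)
  tt <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in tt) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V == 0) return(0)
  (O1 - E1)^2 / V
}

# Exact permutation p-value of the log-rank statistic (all label
# reassignments preserving group sizes; feasible for <= 8 observations).
oracle_logrank_perm_p <- function(time, event, group) {
  g <- as.integer(factor(group))
  n1 <- sum(g == 1)
  obs <- oracle_logrank_chisq(time, event, g)
  combs <- utils::combn(length(g), n1)
  stats <- apply(combs, 2, function(idx) {
    gg <- rep(2L, length(g)); gg[idx] <- 1L
    oracle_logrank_chisq(time, event, gg)
  })
  mean(stats >= obs - 1e-12)
}

# Product-limit estimator by direct recursion.
oracle_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(tt))
  for (i in seq_along(tt)) {
    n <- sum(time >= tt[i])
    d <- sum(event == 1 & time == tt[i])
    s <- s * (1 - d / n)
    surv[i] <- s
  }
  data.frame(time = tt, surv = surv)
}

# Literal truth table of the pathogenicity rules.
oracle_pathogenic <- function(type, splice_ai = NA, splice_effect = NA,
                              clinvar = NA, sift = NA, polyphen2 = NA) {
  type_rule <- c("nonsense", "stop_loss", "start_loss", "frameshift_indel",
                 "nonframeshift_indel", "block_substitution")
  if (type %in% type_rule) return(TRUE)
  if (type == "splice_site") {
    if (is.na(splice_ai)) return(NA)
    return(splice_ai >= 0.5 && !is.na(splice_effect) &&
             splice_effect %in% c("acceptor_loss", "acceptor_gain",
                                  "donor_loss", "donor_gain"))
  }
  # missense
  if (is.na(clinvar) && is.na(sift) && is.na(polyphen2)) return(NA)
  isTRUE(clinvar) || (!is.na(sift) && sift <= 0.05) ||
    (!is.na(polyphen2) && polyphen2 >= 0.5)
}

# Direct expected-count rule for the chi-square/Fisher switch.
oracle_select_test <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (sum(e < 5) / length(e) >= 0.25) "fisher" else "chi_square"
}

# Allele-pool expected mirrored BAF at a germline het 3p locus.
oracle_mirrored_baf <- function(state, purity) {
  switch(state,
         retention = 0.5,
         loss = 1 / (2 - purity),
         isodisomy = (1 + purity) / 2)
}

# Schoenfeld events-based power (exponential margins, administrative
# censoring at the horizon).
oracle_schoenfeld <- function(n1, n2, s1, s2, alpha = 0.05) {
  d <- n1 * (1 - s1) + n2 * (1 - s2)
  p1 <- n1 / (n1 + n2)
  hr <- log(s2) / log(s1)
  pnorm(sqrt(d * p1 * (1 - p1)) * abs(log(hr)) - qnorm(1 - alpha / 2))
}
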
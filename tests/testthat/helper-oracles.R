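# Independent brute-force oracles used to validate the package's own
# implementations. These deliberately share no code with R/.

# total within-cluster sum of squares of a set of rows about its mean
ssd_about_mean <- function(M) {
  if (nrow(M) == 0L) return(0)
  mu <- colMeans(M)
  s <- 0
  for (i in seq_len(nrow(M))) s <- s + sum((M[i, ] - mu)^2)
  s
}

# exhaustive minimum WSS over all 2-partitions (both parts non-empty)
exhaustive_2partition_wss <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  best <- Inf
  # fix row 1 in part A to halve the space; exclude the empty-B mask
  for (mask in 0:(2^(n - 1) - 2)) {
    inA <- c(TRUE, as.logical(bitwAnd(mask, 2^(0:(n - 2))) > 0))
    w <- ssd_about_mean(X[inA, , drop = FALSE]) +
      ssd_about_mean(X[!inA, , drop = FALSE])
    if (w < best) best <- w
  }
  best
}

# naive double-loop Calinski-Harabasz
naive_ch <- function(X, assignment) {
  X <- as.matrix(X)
  n <- nrow(X)
  cl <- sort(unique(assignment))
  k <- length(cl)
  grand <- colMeans(X)
  W <- 0
  B <- 0
  for (j in cl) {
    rows <- which(assignment == j)
    cj <- colMeans(X[rows, , drop = FALSE])
    for (i in rows) W <- W + sum((X[i, ] - cj)^2)
    B <- B + length(rows) * sum((cj - grand)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

# exact two-sided rank-sum p by full enumeration of group memberships
# (tie-free data only); returns the same two-sided convention as the
# distribution-based exact test: 2 * min(P(U <= u), P(U >= u)), capped at 1
enumerated_wilcoxon_p <- function(x1, x2) {
  n1 <- length(x1)
  pool <- c(x1, x2)
  stopifnot(!anyDuplicated(pool))
  u_obs <- sum(outer(x1, x2, ">"))
  picks <- utils::combn(length(pool), n1)
  us <- apply(picks, 2L, function(idx)
    sum(outer(pool[idx], pool[-idx], ">")))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(p, 1)
}

# small two-subtype cohort spec with explicit moments, for generator tests
toy_spec <- function(n = c(MMNS = 5L, SMNS = 5L),
                     means = rbind(age_onset = c(50, 60), m1 = c(1, 3),
                                   nm1 = c(2, 6), nm_rev = c(20, 10)),
                     sds = means * 0, maxs = c(Inf, 10, 10, 30),
                     integer_valued = FALSE, longitudinal = NULL,
                     missingness = NULL, seed = 1L) {
  labs <- names(n)
  schema <- data.frame(
    name = rownames(means),
    category = c("age", "motor", "nonmotor", "nonmotor"),
    min = 0, max = maxs, integer = integer_valued,
    direction = c("higher_worse", "higher_worse", "higher_worse",
                  "higher_better"))
  colnames(means) <- colnames(sds) <- labs
  cohort_spec(data.frame(label = labs, n = unname(n)), schema,
              means, sds, missingness = missingness,
              longitudinal = longitudinal, seed = seed)
}

# longitudinal block helper: same moments for both subtypes unless given
toy_longitudinal <- function(hy_base = c(1.5, 0), hy_early = c(0.228, 0),
                             hy_sec = c(0.169, 0), moca_base = c(15, 0),
                             moca_early = c(-0.693, 0),
                             moca_sec = c(0.254, 0), dropout = 0L,
                             labels = c("MMNS", "SMNS")) {
  pair <- function(ms) setNames(rep(list(list(mean = ms[1], sd = ms[2])),
                                    length(labels)), labels)
  list(dropout = dropout,
       hy = list(scale = list(min = 0, max = 5),
                 baseline = pair(hy_base), early = pair(hy_early),
                 secondary = pair(hy_sec)),
       moca = list(scale = list(min = 0, max = 30),
                   baseline = pair(moca_base), early = pair(moca_early),
                   secondary = pair(moca_sec)))
}
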
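# Independent brute-force oracles. These deliberately take the naive
# enumeration route (materializing every arrangement) so they share no code
# with the package's generating-function implementation.

# Exact two-sided rank-sum p by enumerating every choose(m+n, m) assignment
# of the pooled mid-ranks to the first group.
oracle_rank_sum_p <- function(x, y,
                              alternative = c("two.sided", "less",
                                              "greater")) {
  alternative <- match.arg(alternative)
  m <- length(x)
  ranks <- rank(c(x, y))
  W <- sum(ranks[seq_len(m)])
  sums <- combn(ranks, m, sum)
  p_lower <- mean(sums <= W + 1e-9)
  p_upper <- mean(sums >= W - 1e-9)
  switch(alternative,
         two.sided = min(1, 2 * min(p_lower, p_upper)),
         less = p_lower, greater = p_upper)
}

# Exact two-sided signed-rank p by enumerating all 2^n sign patterns on the
# mid-ranks of |differences| (zeros already removed by the caller).
oracle_signed_rank_p <- function(d,
                                 alternative = c("two.sided", "less",
                                                 "greater")) {
  alternative <- match.arg(alternative)
  d <- d[d != 0]
  n <- length(d)
  ranks <- rank(abs(d))
  V <- sum(ranks[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  sums <- as.vector(signs %*% ranks)
  p_lower <- mean(sums <= V + 1e-9)
  p_upper <- mean(sums >= V - 1e-9)
  switch(alternative,
         two.sided = min(1, 2 * min(p_lower, p_upper)),
         less = p_lower, greater = p_upper)
}

# Checks the compact-letter-display invariant directly: two groups share a
# letter iff their comparison is not significant.
oracle_letters_valid <- function(cl, pw, alpha) {
  for (r in seq_len(nrow(pw))) {
    a <- pw$group_i[r]; b <- pw$group_j[r]
    shared <- length(intersect(cl$assignment[[a]], cl$assignment[[b]])) > 0
    want_shared <- !(pw$p_value[r] < alpha)
    if (shared != want_shared) return(FALSE)
  }
  TRUE
}

# A complete random pairwise significance pattern over k named groups.
random_pairwise <- function(k, seed) {
  set.seed(seed)
  labs <- paste0("g", seq_len(k))
  pairs <- t(combn(labs, 2))
  data.frame(group_i = pairs[, 1], group_j = pairs[, 2],
             p_value = ifelse(runif(nrow(pairs)) < 0.5,
                              runif(nrow(pairs), 0, 0.04),
                              runif(nrow(pairs), 0.06, 1)),
             stringsAsFactors = FALSE)
}

# Small noise-free scene used across quantification tests.
quiet_scene <- function(transmittance = 0.7, count = 0L, seed = 11L,
                        noise = 0, ...) {
  render_scene(scene_params(noise_sd = noise,
                            tissue_transmittance = transmittance,
                            iridophore_count = count, seed = seed, ...),
               subject_id = "t1", group_label = "grp")
}
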
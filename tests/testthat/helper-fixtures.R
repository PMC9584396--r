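# Small configurations reused across tests.

tiny_config <- function(seed = 1L, ...) {
  args <- list(...)
  if (is.null(args$n_genes)) args$n_genes <- 50L
  if (is.null(args$n_de_genes)) args$n_de_genes <- 5L
  do.call(sim_config, c(list(seed = seed), args))
}

study_config <- function(seed = 1L, ...) {
  # the emulated study's design: 2000-gene array, 200 planted DE genes,
  # 11 cases vs 18 controls
  sim_config(seed = seed, ...)
}

extdata <- function(file) {
  system.file("extdata", file, package = "ibstriage", mustWork = TRUE)
}

# Brute-force two-tailed Mann-Whitney p by enumerating every assignment of
# ranks to group x (independent of the pwilcox-based implementation path).
enumerate_mw_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  all_u <- apply(utils::combn(nx + ny, nx), 2, function(idx) {
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  lower <- mean(all_u <= u_obs)
  upper <- mean(all_u >= u_obs)
  min(1, 2 * min(lower, upper))
}

# Literal evaluation of the percent-accuracy formula, kept deliberately
# separate from the package implementation.
literal_percent_accuracy <- function(x, y) {
  total <- 0
  for (i in seq_along(x)) total <- total + x[i] / y[i]
  round(100 * total / length(x), 2)
}

# Brute-force upper-tail hypergeometric probability by direct summation.
brute_hyper_tail <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
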
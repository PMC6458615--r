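#' Build a family-by-genome presence/absence (copy-count) matrix
#'
#' @param families data frame with columns `family_id`, `strain` (one row
#'   per gene), e.g. from [cluster_families()] or a truth table.
#' @param genomes optional genome ids fixing column order (and including
#'   genomes with zero genes).
#' @return Integer matrix of copy counts, families x genomes.
#' @export
presence_absence_matrix <- function(families, genomes = NULL) {
  if (is.null(genomes)) genomes <- sort(unique(families$strain))
  tab <- table(factor(families$family_id),
               factor(families$strain, levels = genomes))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}

#' Pan- and core-genome accumulation curves
#'
#' For each of `n_permutations` random genome orderings, computes
#' `pan(n)` = families present in at least one of the first `n` genomes and
#' `core(n)` = families present in all of the first `n`, then averages over
#' orderings. Error bars are standard deviations over orderings.
#'
#' @param matrix presence/absence matrix from [presence_absence_matrix()].
#' @param n_permutations number of random orderings (>= 1).
#' @param seed RNG seed.
#' @return Object of class `accumulation_curve`: data frame with columns
#'   `n`, `pan_mean`, `pan_sd`, `core_mean`, `core_sd` plus attributes
#'   `n_permutations` and `seed`.
#' @export
accumulation_curves <- function(matrix, n_permutations = 100, seed = 1) {
  if (is.null(dim(matrix)) || nrow(matrix) == 0 || ncol(matrix) == 0)
    stop("empty presence/absence matrix")
  if (ncol(matrix) < 2) stop("need at least 2 genomes")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  pres <- matrix > 0
  N <- ncol(pres)
  pan <- core <- matrix(0L, nrow = n_permutations, ncol = N)
  with_seed(seed, {
    for (p in seq_len(n_permutations)) {
      ord <- sample.int(N)
      seen <- rep(FALSE, nrow(pres))
      inall <- rep(TRUE, nrow(pres))
      for (n in seq_len(N)) {
        col <- pres[, ord[n]]
        seen <- seen | col
        inall <- inall & col
        pan[p, n] <- sum(seen)
        core[p, n] <- sum(inall)
      }
    }
  })
  out <- data.frame(n = seq_len(N),
                    pan_mean = colMeans(pan),
                    pan_sd = apply(pan, 2, sd),
                    core_mean = colMeans(core),
                    core_sd = apply(core, 2, sd))
  attr(out, "n_permutations") <- n_permutations
  attr(out, "seed") <- seed
  class(out) <- c("accumulation_curve", "data.frame")
  out
}

#' Fit Heap's law to a pan-genome accumulation curve
#'
#' Ordinary least squares on the log-log scale:
#' `log(pan_mean) = log(kappa) + gamma * log(n)`, matching the power law
#' `P(n) = kappa * n^gamma`. A positive exponent `gamma` classifies the
#' pan-genome as open (it keeps growing as genomes are added).
#'
#' @param curve an [accumulation_curves()] result, or any data frame with
#'   columns `n` and `pan_mean`.
#' @return List with `kappa`, `gamma`, `r_squared`, and `open` (logical).
#' @export
fit_heaps <- function(curve) {
  if (nrow(curve) < 3) stop("need at least 3 points to fit Heap's law")
  if (any(curve$pan_mean <= 0)) stop("pan_mean must be strictly positive")
  fit <- lm(log(pan_mean) ~ log(n), data = curve)
  co <- coef(fit)
  # suppressed: summary.lm warns on noiseless (perfect-fit) curves
  r2 <- suppressWarnings(summary(fit)$r.squared)
  # openness calls gamma > 0 with a tolerance absorbing least-squares
  # round-off on exactly flat curves
  list(kappa = unname(exp(co[1])), gamma = unname(co[2]),
       r_squared = r2, open = unname(co[2]) > 1e-9)
}

#' Fit an exponential decay model to the core-genome curve
#'
#' Nonlinear least squares of `C(n) = Omega + A * exp(-n / tau)`, where
#' `Omega` is the predicted minimum core size as genomes accumulate.
#' Multi-start initialization over `tau0`; the best-loss fit is returned.
#' Exactly constant curves short-circuit to `Omega = C, A = 0`.
#'
#' @param curve an [accumulation_curves()] result, or any data frame with
#'   columns `n` and `core_mean`.
#' @param tau_starts initial decay constants to try.
#' @return List with `Omega`, `A`, `tau`, `rss`.
#' @export
fit_core_decay <- function(curve, tau_starts = c(1, 3, 10)) {
  n <- curve$n
  y <- curve$core_mean
  if (length(y) < 3) stop("need at least 3 points to fit core decay")
  if (sd(y) == 0)
    return(list(Omega = y[1], A = 0, tau = Inf, rss = 0))
  omega0 <- min(y)
  a0 <- max(y[1] - omega0, 1e-6)
  fits <- list()
  errs <- character(0)
  for (tau0 in tau_starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(y ~ Omega + A * exp(-n / tau),
                        start = list(Omega = omega0, A = a0, tau = tau0),
                        lower = c(Omega = 0, A = 0, tau = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(f, "error")) errs <- c(errs, conditionMessage(f))
    else fits[[length(fits) + 1L]] <- f
  }
  if (length(fits) == 0)
    stop("core decay fit failed for all starts: ",
         paste(unique(errs), collapse = "; "))
  rss <- vapply(fits, function(f) sum(residuals(f)^2), 0)
  best <- fits[[which.min(rss)]]
  co <- coef(best)
  list(Omega = unname(co["Omega"]), A = unname(co["A"]),
       tau = unname(co["tau"]), rss = min(rss))
}

#' Singleton family statistics
#'
#' Counts pan-genome families present in exactly one genome (any copy
#' number) and their fraction of the pan-genome.
#'
#' @param matrix presence/absence matrix.
#' @return List with `n_singleton` and `fraction`.
#' @export
singleton_stats <- function(matrix) {
  if (is.null(dim(matrix)) || nrow(matrix) == 0)
    stop("empty presence/absence matrix")
  n_genomes_with <- rowSums(matrix > 0)
  n_singleton <- sum(n_genomes_with == 1)
  list(n_singleton = n_singleton, fraction = n_singleton / nrow(matrix))
}
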
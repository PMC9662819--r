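#' Simulate a labelled residue feature matrix
#'
#' Class-conditional Gaussian stand-in for the 27-column site feature
#' matrix: feature `j` is drawn from `Normal(effects[j], sigma[j])` for
#' hotspot residues and `Normal(0, sigma[j])` for the rest, so the
#' population F score of feature `j` is `|effects[j]| / (2 * sigma[j])`.
#'
#' @param n_res Number of residues.
#' @param labels Binary vector of length `n_res` (1 = hotspot).
#' @param effects Numeric vector of 27 per-feature mean shifts
#'   (recycled if length 1).
#' @param sigma Numeric vector of 27 per-feature standard deviations
#'   (recycled if length 1).
#' @param seed Integer seed.
#' @return A `data.frame` with `residue`, the 27 registry feature
#'   columns and `label`.
#' @export
generate_feature_matrix <- function(n_res, labels, effects = 0,
                                    sigma = 1, seed = 1L) {
  n_res <- assert_count(n_res, "n_res")
  if (length(labels) != n_res) {
    stopf("`labels` must have length n_res (%d), got %d",
          n_res, length(labels))
  }
  if (!all(labels %in% c(0, 1))) stopf("labels must be binary")
  nm <- feature_names()
  effects <- rep_len(effects, length(nm))
  sigma <- rep_len(sigma, length(nm))
  if (any(sigma < 0)) stopf("sigma must be non-negative")
  with_seed(seed, {
    cols <- lapply(seq_along(nm), function(jj) {
      stats::rnorm(n_res, mean = effects[jj] * labels, sd = sigma[jj])
    })
    names(cols) <- nm
    out <- data.frame(residue = seq_len(n_res), cols,
                      label = as.integer(labels))
    validate_feature_matrix(out)
    out
  })
}

#' Describe a synthetic homolog family
#'
#' Members of the family share a common logistic labelling rule on
#' their 27 standard-normal features; each member's coefficient vector
#' is the shared rule plus an independent Gaussian perturbation of
#' scale `divergence`, emulating homologs whose allosteric logic is
#' conserved in outline but divergent in detail. The logistic intercept
#' of each member is calibrated so the expected hotspot fraction equals
#' `prevalence`.
#'
#' @param n_proteins Number of family members (>= 2).
#' @param n_residues Residues per member.
#' @param shared_rule Numeric vector of 27 shared coefficients. The
#'   default puts weight on six global features (motional correlations,
#'   distances to the functional sites and centrality peaks), the
#'   pattern the real screens point to.
#' @param divergence Standard deviation of the per-protein coefficient
#'   perturbation (0 = identical rules).
#' @param prevalence Expected hotspot fraction, in (0, 1).
#' @param seed Integer seed.
#' @return A list of class `homolog_family_scenario`.
#' @export
homolog_family_scenario <- function(n_proteins = 4L, n_residues = 200L,
                                    shared_rule = default_shared_rule(),
                                    divergence = 0.35, prevalence = 0.25,
                                    seed = 1L) {
  n_proteins <- assert_count(n_proteins, "n_proteins", min = 2L)
  n_residues <- assert_count(n_residues, "n_residues")
  shared_rule <- rep_len(as.numeric(shared_rule), 27L)
  if (divergence < 0) stopf("divergence must be >= 0")
  if (prevalence <= 0 || prevalence >= 1) {
    stopf("prevalence must be in (0, 1)")
  }
  structure(list(n_proteins = n_proteins, n_residues = n_residues,
                 shared_rule = shared_rule, divergence = divergence,
                 prevalence = prevalence,
                 seed = assert_count(seed, "seed", min = 0L)),
            class = "homolog_family_scenario")
}

#' @rdname homolog_family_scenario
#' @export
default_shared_rule <- function() {
  rule <- numeric(27L)
  nm <- feature_names()
  rule[nm == "corr_dna"] <- 1.2
  rule[nm == "max_correlation"] <- 1.0
  rule[nm == "dist_dna"] <- -1.2
  rule[nm == "dist_ligand"] <- -1.0
  rule[nm == "dist_peak1"] <- 1.0
  rule[nm == "dist_peak3"] <- 0.8
  rule
}

#' Simulate a family of homolog feature matrices
#'
#' @param scenario A [homolog_family_scenario()].
#' @return A list with one element per protein, each a list of
#'   `features` (a labelled feature `data.frame` as produced by the
#'   structural stack), `labels`, and the realized coefficient vector
#'   `rule`.
#' @export
generate_homolog_family <- function(scenario) {
  stopifnot(inherits(scenario, "homolog_family_scenario"))
  s <- scenario
  with_seed(s$seed, {
    lapply(seq_len(s$n_proteins), function(k) {
      beta <- s$shared_rule + stats::rnorm(27L, sd = s$divergence)
      x <- matrix(stats::rnorm(s$n_residues * 27L), ncol = 27L,
                  dimnames = list(NULL, feature_names()))
      eta <- drop(x %*% beta)
      a <- logistic_intercept(sqrt(sum(beta^2)), s$prevalence)
      labels <- as.integer(stats::runif(s$n_residues) <
                             stats::plogis(a + eta))
      fm <- data.frame(residue = seq_len(s$n_residues), x,
                       label = labels, check.names = FALSE)
      list(features = fm, labels = labels, rule = beta)
    })
  })
}

## Intercept a such that E[plogis(a + s * Z)] = prevalence for Z ~ N(0,1).
logistic_intercept <- function(s, prevalence) {
  if (s == 0) return(stats::qlogis(prevalence))
  f <- function(a) {
    stats::integrate(function(z) stats::plogis(a + s * z) * stats::dnorm(z),
                     -Inf, Inf)$value - prevalence
  }
  stats::uniroot(f, interval = c(-30, 30))$root
}
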
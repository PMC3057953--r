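#' Substitution model for the sequence simulator
#'
#' Two modes. `homogeneous`: one equilibrium frequency vector and a
#' symmetric exchangeability matrix (uniform by default) shared by all
#' sites. `profile_mixture`: a CAT-like site-heterogeneous model where
#' each site draws its equilibrium frequencies from one of K profiles
#' (uniform exchangeabilities, the CAT convention: profiles differ only
#' in which states they accept). Either mode can add gamma rate
#' variation across sites (discrete, 4 categories, equal-probability
#' quantile means) and per-gene rate multipliers.
#'
#' @param s alphabet size: 4 (nucleotide) or 20 (amino acid).
#' @param mode `"homogeneous"` or `"profile_mixture"`.
#' @param freqs equilibrium frequencies (homogeneous mode); default uniform.
#' @param exchangeabilities symmetric s x s matrix of relative rates
#'   (homogeneous mode); default uniform. The diagonal is ignored.
#' @param profiles K x s matrix of frequency profiles (mixture mode).
#' @param weights mixture weights (default uniform over profiles).
#' @param gamma_shape gamma shape a > 0, or `NULL` for uniform rates.
#' @param gene_rates numeric vector of per-gene rate multipliers,
#'   recycled over genes at simulation time (default 1).
#' @return an object of class `substitution_model`.
#' @export
substitution_model <- function(s = 4,
                               mode = c("homogeneous", "profile_mixture"),
                               freqs = NULL, exchangeabilities = NULL,
                               profiles = NULL, weights = NULL,
                               gamma_shape = NULL, gene_rates = 1) {
  mode <- match.arg(mode)
  if (!s %in% c(4, 20)) stop("alphabet size s must be 4 or 20")
  check_freq <- function(f, what) {
    if (length(f) != s) stop(what, " must have length s = ", s)
    if (any(f < 0) || abs(sum(f) - 1) > 1e-12) {
      stop(what, " must be non-negative and sum to 1 (within 1e-12)")
    }
    f
  }
  if (mode == "homogeneous") {
    if (is.null(freqs)) freqs <- rep(1 / s, s)
    freqs <- check_freq(freqs, "freqs")
    if (is.null(exchangeabilities)) {
      exchangeabilities <- matrix(1, s, s)
    }
    if (!isSymmetric(unname(exchangeabilities))) {
      stop("exchangeabilities must be symmetric")
    }
    profiles <- matrix(freqs, nrow = 1L)
    weights <- 1
  } else {
    if (is.null(profiles)) stop("profile_mixture mode needs profiles")
    profiles <- as.matrix(profiles)
    if (ncol(profiles) != s) stop("profiles must have s = ", s, " columns")
    for (k in seq_len(nrow(profiles))) check_freq(profiles[k, ], "profile")
    if (is.null(weights)) weights <- rep(1 / nrow(profiles), nrow(profiles))
    if (length(weights) != nrow(profiles) || any(weights < 0) ||
        abs(sum(weights) - 1) > 1e-12) {
      stop("weights must be non-negative and sum to 1 (within 1e-12)")
    }
    exchangeabilities <- matrix(1, s, s)  # CAT convention
  }
  if (!is.null(gamma_shape) && (!is.finite(gamma_shape) || gamma_shape <= 0)) {
    stop("gamma_shape must be a finite positive number")
  }
  if (any(gene_rates <= 0)) stop("gene_rates must be positive")
  structure(list(s = s, mode = mode, profiles = profiles, weights = weights,
                 exchangeabilities = exchangeabilities,
                 gamma_shape = gamma_shape, gene_rates = gene_rates),
            class = "substitution_model")
}

#' Random CAT-like frequency profiles
#'
#' Draws K sparse frequency profiles from a symmetric Dirichlet. The
#' default concentration 0.2 over 20 states gives profiles with roughly
#' 3-6 effectively accepted amino acids, the regime empirical CAT
#' profiles occupy, and therefore substantial convergent evolution
#' (homoplasy) when long branches are simulated.
#'
#' @param K number of profiles.
#' @param s alphabet size.
#' @param concentration symmetric Dirichlet parameter.
#' @param seed integer seed.
#' @return K x s matrix of frequencies, rows summing to 1.
#' @export
cat_profiles <- function(K = 10L, s = 20L, concentration = 0.2, seed = 1L) {
  set.seed(seed)
  g <- matrix(stats::rgamma(K * s, shape = concentration), nrow = K)
  # guard against an all-zero draw at tiny concentration
  g[rowSums(g) == 0, 1L] <- 1
  p <- g / rowSums(g)
  p / rowSums(p)
}

#' Simulation specification
#'
#' Bundles everything [simulate_supermatrix()] needs: the generating
#' tree (branch lengths in expected substitutions per site at a site's
#' own rate), the substitution model, gene layout, and master seed.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param model a [substitution_model()].
#' @param sites_per_gene sites in each gene (scalar or per-gene vector).
#' @param n_genes number of genes.
#' @param seed explicit integer master seed.
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(tree, model, sites_per_gene = 1000L,
                            n_genes = 1L, seed) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "substitution_model"))
  if (missing(seed)) stop("an explicit seed is required")
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  sites <- rep_len(as.integer(sites_per_gene), n_genes)
  if (any(sites < 1L)) stop("sites_per_gene must be >= 1")
  structure(list(tree = tree, model = model, sites = sites,
                 n_genes = as.integer(n_genes), seed = as.integer(seed)),
            class = "simulation_spec")
}
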
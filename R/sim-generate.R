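# --- rate-matrix machinery -------------------------------------------------

# Reversible rate matrix from exchangeabilities and frequencies,
# normalized to one expected substitution per unit branch length.
normalized_q <- function(exch, freqs) {
  s <- length(freqs)
  q <- exch * rep(freqs, each = s)
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  beta <- -sum(freqs * diag(q))
  if (beta <= 0) stop("degenerate rate matrix (a frequency vector with one 1 is fine only in mixture profiles)")
  q / beta
}

# Single-branch evolution kernel for one frequency vector: returns
# step(x, t), drawing the child state given parent state x and scaled
# branch length t. Uniform exchangeabilities admit the closed F81-type
# form P(t) = exp(-t/beta) I + (1 - exp(-t/beta)) 1 pi' with
# beta = 1 - sum(pi^2), so the child either keeps the parent state
# (probability exp(-t/beta)) or redraws from the profile; the general
# symmetric case goes through a stable eigendecomposition of the
# similarity-transformed generator.
transition_step <- function(exch, freqs) {
  s <- length(freqs)
  off <- exch[upper.tri(exch)]
  uniform <- all(abs(off - off[1L]) < 1e-12)
  if (uniform) {
    beta <- 1 - sum(freqs^2)
    if (beta <= 0) {
      # a degenerate profile (one state has frequency 1): nothing moves
      return(function(x, t) x)
    }
    return(function(x, t) {
      if (stats::runif(1) < exp(-t / beta)) x
      else sample.int(s, 1L, prob = freqs)
    })
  }
  q <- normalized_q(exch, freqs)
  if (!all(freqs > 0)) {
    stop("general exchangeabilities need strictly positive frequencies")
  }
  dh <- sqrt(freqs)
  b <- diag(dh) %*% q %*% diag(1 / dh)
  eg <- eigen((b + t(b)) / 2, symmetric = TRUE)
  V <- diag(1 / dh) %*% eg$vectors
  Vi <- t(eg$vectors) %*% diag(dh)
  function(x, t) {
    row <- V[x, ] %*% (exp(eg$values * t) * Vi)
    row[row < 0] <- 0
    sample.int(s, 1L, prob = row)
  }
}

# Discrete-gamma category rates (4 categories, equal-probability
# quantile-mean method); NULL shape means uniform rates.
gamma_category_rates <- function(shape, k = 4L) {
  if (is.null(shape)) return(1)
  phangorn::discrete.gamma(shape, k)
}

# Stream seed for a (gene, site) pair, derived from the master seed so
# that adding genes or sites never perturbs previously generated data.
# Mixes through two rounds of a Lehmer-style multiplicative hash kept
# in double precision below 2^31.
derive_site_seed <- function(master, gene, site) {
  m <- 2147483647
  h <- (abs(master) %% m)
  h <- (h * 48271 + gene * 69621 + 1) %% m
  h <- (h * 48271 + site * 16807 + 1) %% m
  as.integer(h)
}

# --- the simulator ---------------------------------------------------------

#' Simulate a multi-gene supermatrix with known ground truth
#'
#' Evolves sequences down the spec's tree one site at a time. Each site
#' draws (from its own random stream keyed by gene and site) a mixture
#' profile, a discrete-gamma rate category, a root state from the
#' profile frequencies, and then child states edge by edge in preorder
#' under the continuous-time model whose off-diagonal rates are
#' exchangeability times target frequency, normalized so a branch length
#' is the expected number of substitutions per site at that site's rate.
#' The site rate is the gamma category rate times the gene multiplier.
#' The same spec and seed always give a byte-identical supermatrix.
#'
#' @param spec a [simulation_spec()].
#' @return list with `supermatrix` (one partition per gene, genes named
#'   `gene01`, ...) and `truth`, a data.frame (gene, site, profile,
#'   rate) of the per-site generating conditions.
#' @export
simulate_supermatrix <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  tree <- spec$tree
  model <- spec$model
  alphabet <- if (model$s == 4) "nt" else "aa"
  states <- residue_states(alphabet)
  K <- nrow(model$profiles)
  cat_rates <- gamma_category_rates(model$gamma_shape)
  n_cat <- length(cat_rates)
  pfn <- lapply(seq_len(K), function(k) {
    transition_step(model$exchangeabilities, model$profiles[k, ])
  })
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  pre_edges <- rev(seq_len(nrow(po$edge)))  # preorder = reversed postorder
  root <- po$edge[nrow(po$edge), 1L]
  gene_rates <- rep_len(model$gene_rates, spec$n_genes)
  genes <- vector("list", spec$n_genes)
  names(genes) <- sprintf("gene%02d", seq_len(spec$n_genes))
  truth <- vector("list", spec$n_genes)
  n_nodes <- ntip + tree$Nnode
  for (g in seq_len(spec$n_genes)) {
    L <- spec$sites[g]
    m <- matrix(NA_integer_, nrow = ntip, ncol = L)
    prof_id <- integer(L)
    rate_used <- numeric(L)
    for (site in seq_len(L)) {
      set.seed(derive_site_seed(spec$seed, g, site))
      k <- if (K == 1L) 1L else sample.int(K, 1L, prob = model$weights)
      cat <- if (n_cat == 1L) 1L else sample.int(n_cat, 1L)
      rate <- cat_rates[cat] * gene_rates[g]
      prof_id[site] <- k
      rate_used[site] <- rate
      step <- pfn[[k]]
      state <- integer(n_nodes)
      state[root] <- sample.int(model$s, 1L, prob = model$profiles[k, ])
      for (e in pre_edges) {
        par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
        t <- po$edge.length[e] * rate
        state[ch] <- if (t == 0) state[par] else step(state[par], t)
      }
      m[, site] <- state[seq_len(ntip)]
    }
    chr <- matrix(states[m], nrow = ntip,
                  dimnames = list(po$tip.label, NULL))
    genes[[g]] <- msa(chr, alphabet = alphabet)
    truth[[g]] <- data.frame(gene = names(genes)[g], site = seq_len(L),
                             profile = prof_id, rate = rate_used,
                             stringsAsFactors = FALSE)
  }
  list(supermatrix = concatenate(genes), truth = do.call(rbind, truth))
}
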
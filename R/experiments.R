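#' Taxon-sampling experiment specification
#'
#' Describes a family of reanalyses of one supermatrix: named
#' conditions, each defined by the taxa it keeps; named focal clades
#' whose support is tracked; and either inference settings (the internal
#' distance + bootstrap engine is run per condition) or externally
#' supplied per-condition trees (e.g. from ML or Bayesian programs,
#' ingested as Newick), in which case no inference happens at all.
#'
#' @param sm the base [supermatrix].
#' @param conditions named list of taxon keep-sets (each >= 4 taxa).
#' @param clades named list of focal taxon sets (subsets of the base taxa).
#' @param model a [distance_model()] for internal inference.
#' @param B bootstrap replicates for internal inference.
#' @param seed integer seed.
#' @param trees optional named list of `phylo` trees, one per condition;
#'   when given, supports are read from these trees verbatim.
#' @return an object of class `experiment_spec`.
#' @export
experiment_spec <- function(sm, conditions, clades, model = distance_model("poisson"),
                            B = 100L, seed = 1L, trees = NULL) {
  stopifnot(is_supermatrix(sm))
  if (!length(conditions) || is.null(names(conditions))) {
    stop("conditions must be a named list of taxon sets")
  }
  if (!length(clades) || is.null(names(clades))) {
    stop("clades must be a named list of taxon sets")
  }
  base <- taxa_names(sm)
  for (nm in names(conditions)) {
    unknown <- setdiff(conditions[[nm]], base)
    if (length(unknown)) {
      stop("condition ", nm, " names unknown taxa: ",
           paste(unknown, collapse = ", "))
    }
    if (length(conditions[[nm]]) < 4L) {
      stop("condition ", nm, " keeps fewer than 4 taxa")
    }
  }
  for (nm in names(clades)) {
    unknown <- setdiff(clades[[nm]], base)
    if (length(unknown)) {
      stop("clade ", nm, " names unknown taxa: ",
           paste(unknown, collapse = ", "))
    }
  }
  if (!is.null(trees)) {
    missing_t <- setdiff(names(conditions), names(trees))
    if (length(missing_t)) {
      stop("no tree supplied for condition(s): ",
           paste(missing_t, collapse = ", "))
    }
  }
  structure(list(sm = sm, conditions = conditions, clades = clades,
                 model = model, B = as.integer(B), seed = as.integer(seed),
                 trees = trees),
            class = "experiment_spec")
}

#' Run a taxon-sampling experiment
#'
#' For each condition the supermatrix is subset to the kept taxa and a
#' bootstrap-supported tree is obtained (internal engine, or the
#' externally supplied tree for that condition). Each focal clade is
#' then evaluated on its surviving members only — mirroring how, e.g.,
#' sponge monophyly is compared across samplings that keep different
#' sponges. Clades reduced to fewer than 2 survivors are reported
#' `not_evaluable`; clades whose split is not in the tree are `absent`.
#'
#' @param spec an [experiment_spec()].
#' @return data.frame with one row per condition x clade: `condition`,
#'   `clade`, `support` (numeric, NA unless status is `"ok"`), `status`
#'   in `ok` / `absent` / `not_evaluable`.
#' @export
run_conditions <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  rows <- list()
  for (cn in names(spec$conditions)) {
    keep <- spec$conditions[[cn]]
    tr <- if (!is.null(spec$trees)) {
      spec$trees[[cn]]
    } else {
      sub <- subset_taxa(spec$sm, keep)
      bootstrap_support(sub, B = spec$B,
                        seed = spec$seed + match(cn, names(spec$conditions)) * 10000L,
                        model = spec$model)
    }
    for (kn in names(spec$clades)) {
      surv <- intersect(spec$clades[[kn]], tr$tip.label)
      if (length(surv) < 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cn, clade = kn, support = NA_real_,
          status = "not_evaluable", stringsAsFactors = FALSE)
        next
      }
      if (length(surv) >= length(tr$tip.label) - 1L) {
        # the survivors span (almost) the whole tree: the split is trivial
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cn, clade = kn, support = NA_real_,
          status = "not_evaluable", stringsAsFactors = FALSE)
        next
      }
      cs <- clade_support(tr, surv)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cn, clade = kn,
        support = if (cs$present) cs$support else NA_real_,
        status = if (cs$present) "ok" else "absent",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Compare conditions against a baseline
#'
#' @param tab output of [run_conditions()].
#' @param baseline name of the baseline condition.
#' @return data.frame per condition x clade with `delta` (numeric
#'   support difference) and a human-readable `change` label; `absent`
#'   and `not_evaluable` states propagate as labels, never as 0.
#' @export
compare_conditions <- function(tab, baseline) {
  if (!baseline %in% tab$condition) stop("unknown baseline condition: ", baseline)
  base <- tab[tab$condition == baseline, c("clade", "support", "status")]
  names(base) <- c("clade", "base_support", "base_status")
  m <- merge(tab, base, by = "clade", sort = FALSE)
  m$delta <- ifelse(m$status == "ok" & m$base_status == "ok",
                    m$support - m$base_support, NA_real_)
  m$change <- with(m, ifelse(
    status == "ok" & base_status == "ok", sprintf("%+g", support - base_support),
    ifelse(status == "not_evaluable", "not evaluable",
    ifelse(status != "ok" & base_status == "ok",
           sprintf("lost (was %g)", base_support),
    ifelse(status == "ok" & base_status != "ok",
           sprintf("gained (%g)", support), "absent in both")))))
  m[order(match(m$condition, unique(tab$condition)),
          match(m$clade, unique(tab$clade))),
    c("condition", "clade", "support", "status", "delta", "change")]
}

#' Outgroup-addition series
#'
#' Evaluates focal-clade support as increasingly distant outgroup
#' groups are added: one condition per prefix of the near-to-far list
#' (closest only; closest + next; ...; all), each analyzed with
#' [run_conditions()] on ingroup + that prefix. Distant outgroups carry
#' long stems and can attract fast-evolving ingroup lineages, so
#' support for genuine ingroup clades often degrades along the series.
#'
#' @param sm the base [supermatrix].
#' @param outgroups ordered (near to far) named list of outgroup taxon
#'   groups, disjoint from the ingroup.
#' @param ingroup ingroup taxon names (non-empty).
#' @param clades named list of focal ingroup clades.
#' @param ... passed to [experiment_spec()] (`model`, `B`, `seed`, `trees`).
#' @return as [run_conditions()], with conditions named
#'   `"+<group1>"`, `"+<group1>+<group2>"`, ...
#' @export
outgroup_series <- function(sm, outgroups, ingroup, clades, ...) {
  if (!length(ingroup)) stop("empty ingroup")
  if (!length(outgroups)) stop("no outgroup groups given")
  if (is.null(names(outgroups))) {
    names(outgroups) <- paste0("og", seq_along(outgroups))
  }
  overlap <- intersect(unlist(outgroups), ingroup)
  if (length(overlap)) {
    stop("outgroups overlap the ingroup: ", paste(overlap, collapse = ", "))
  }
  conds <- list()
  for (k in seq_along(outgroups)) {
    nm <- paste0("+", paste(names(outgroups)[seq_len(k)], collapse = "+"))
    conds[[nm]] <- c(ingroup, unlist(outgroups[seq_len(k)], use.names = FALSE))
  }
  run_conditions(experiment_spec(sm, conds, clades, ...))
}
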
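exp_fixture <- function() {
  ref <- reference10()
  sm <- simulate_supermatrix(simulation_spec(ref, substitution_model(s = 4),
                                             300, 2, seed = 61))$supermatrix
  list(ref = ref, sm = sm)
}

test_that("externally supplied trees are read verbatim, no inference", {
  fx <- exp_fixture()
  lab <- parse_newick(paste0(
    "(((t1:0.1,t2:0.1)96:0.1,(t3:0.1,t4:0.1)88:0.1)77:0.1,",
    "((t5:0.1,t6:0.1)91:0.1,(t7:0.1,t8:0.1)55:0.1)60:0.1,",
    "(t9:0.1,t10:0.1)99:0.1);"))
  spec <- experiment_spec(fx$sm,
                          conditions = list(full = paste0("t", 1:10)),
                          clades = list(pair12 = c("t1", "t2"),
                                        pair56 = c("t5", "t6"),
                                        not_a_clade = c("t1", "t8")),
                          trees = list(full = lab))
  tab <- run_conditions(spec)
  expect_equal(tab$support[tab$clade == "pair12"], 96)
  expect_equal(tab$support[tab$clade == "pair56"], 91)
  expect_equal(tab$status[tab$clade == "not_a_clade"], "absent")
  # bit-stable: run twice, identical output
  expect_identical(tab, run_conditions(spec))
})

test_that("clades reduced below 2 survivors are not evaluable", {
  fx <- exp_fixture()
  lab <- phyloqc:::set_split_supports(fx$ref, local({
    e <- new.env(); for (k in bipartitions(fx$ref)$split) e[[k]] <- 90; e
  }))
  keep <- paste0("t", c(1, 3, 5, 6, 7, 9))
  spec <- experiment_spec(fx$sm,
                          conditions = list(reduced = keep),
                          clades = list(pair12 = c("t1", "t2"),
                                        pair56 = c("t5", "t6")),
                          trees = list(reduced = restrict_tree(lab, keep)))
  tab <- run_conditions(spec)
  expect_equal(tab$status[tab$clade == "pair12"], "not_evaluable")
  expect_equal(tab$status[tab$clade == "pair56"], "ok")
})

test_that("condition validation happens before any inference", {
  fx <- exp_fixture()
  expect_error(experiment_spec(fx$sm, list(tiny = c("t1", "t2", "t3")),
                               list(c12 = c("t1", "t2"))),
               "fewer than 4")
  expect_error(experiment_spec(fx$sm, list(full = c(paste0("t", 1:9), "zz")),
                               list(c12 = c("t1", "t2"))),
               "zz")
  expect_error(experiment_spec(fx$sm, list(full = paste0("t", 1:10)),
                               list(cX = c("t1", "qq"))),
               "qq")
})

test_that("comparisons propagate absences as labels, never zeros", {
  tab <- data.frame(
    condition = rep(c("base", "red"), each = 2),
    clade = rep(c("k1", "k2"), 2),
    support = c(96, 88, 90, NA),
    status = c("ok", "ok", "ok", "absent"),
    stringsAsFactors = FALSE)
  cmp <- compare_conditions(tab, "base")
  self <- cmp[cmp$condition == "base", ]
  expect_true(all(self$delta == 0))
  red <- cmp[cmp$condition == "red", ]
  expect_equal(red$delta[red$clade == "k1"], -6)
  expect_true(is.na(red$delta[red$clade == "k2"]))
  expect_equal(red$change[red$clade == "k2"], "lost (was 88)")
  expect_error(compare_conditions(tab, "nope"), "unknown baseline")
})

test_that("internal inference is deterministic given the seed", {
  fx <- exp_fixture()
  spec <- experiment_spec(fx$sm,
                          conditions = list(full = paste0("t", 1:10),
                                            drop78 = paste0("t", c(1:6, 9, 10))),
                          clades = list(pair12 = c("t1", "t2")),
                          model = distance_model("poisson"), B = 20, seed = 5)
  t1 <- run_conditions(spec)
  t2 <- run_conditions(spec)
  expect_identical(t1, t2)
  expect_true(all(t1$support[t1$status == "ok"] >= 0 &
                  t1$support[t1$status == "ok"] <= 100))
})

test_that("outgroup series builds one condition per near-to-far prefix", {
  ref <- reference10()
  sm <- simulate_supermatrix(simulation_spec(ref, substitution_model(s = 4),
                                             200, 1, seed = 71))$supermatrix
  tab <- outgroup_series(sm,
                         outgroups = list(near = "t9", far = "t10"),
                         ingroup = paste0("t", 1:8),
                         clades = list(pair12 = c("t1", "t2")),
                         B = 10, seed = 3)
  expect_setequal(unique(tab$condition), c("+near", "+near+far"))
  expect_error(outgroup_series(sm, list(near = "t9"), character(0),
                               list(k = c("t1", "t2"))),
               "empty ingroup")
  expect_error(outgroup_series(sm, list(near = "t8"), paste0("t", 1:8),
                               list(k = c("t1", "t2"))),
               "overlap")
})
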
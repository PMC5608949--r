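make_small_data <- function(v, fluid = NULL) {
  fluid <- fluid %||% rep("P", ncol(v))
  mf_data(v, rep("d1", nrow(v)), fluid, log2 = TRUE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("module representatives are average z-scores over the member union", {
  set.seed(1)
  v <- matrix(rnorm(40, 10), 10, 4,
              dimnames = list(sprintf("s%02d", 1:10), paste0("m", 1:4)))
  x <- make_small_data(v)
  ## single metabolite: its z-score
  r1 <- module_representative(x, "P::m1", level = "metabolite")
  expect_equal(unname(r1), as.vector(scale(v[, 1])), tolerance = 1e-12)
  ## two identical members: equals either z-score
  v2 <- v; v2[, 2] <- v2[, 1]
  x2 <- make_small_data(v2)
  r2 <- module_representative(x2, c("P::m1", "P::m2"), "metabolite")
  expect_equal(unname(r2), as.vector(scale(v2[, 1])), tolerance = 1e-12)
})

test_that("pathway-level representatives use the metabolite set union", {
  ## hand-constructed 4-sample table: two pathways with 3 + 2 members
  v <- matrix(c(1, 2, 3, 4,
                2, 1, 4, 3,
                5, 6, 7, 9,
                1, 1, 2, 3,
                4, 3, 2, 1), 4, 5,
              dimnames = list(paste0("s", 1:4), paste0("m", 1:5)))
  ann <- as_annotations(data.frame(
    feature_id = paste0("m", 1:5), fluid = "P",
    sub_pathway = c("A", "A", "A", "B", "B"),
    super_pathway = "S"))
  x <- make_small_data(v)
  r <- module_representative(x, c("P::A", "P::B"), "sub_pathway", ann)
  direct <- rowMeans(scale(v))
  expect_equal(unname(r), unname(direct), tolerance = 1e-12)
  expect_error(module_representative(x, "P::C", "sub_pathway", ann),
               "no member")
})

test_that("a perfect phenotype fit hits the score cap", {
  set.seed(2)
  P <- rnorm(100)
  out <- score_module(P, P)
  expect_equal(out$score, 300)
})

test_that("null scores follow the uniform p-value law", {
  set.seed(3)
  ps <- replicate(200, {
    score_module(rnorm(200), rnorm(200))$p_value
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("scores match the analytic two-sample power oracle", {
  ## binary phenotype, group means 1 SD apart, n = 906: the median score
  ## should match the closed-form median of the noncentral t
  n1 <- 453; n2 <- 453; n <- n1 + n2
  P <- rep(c(0, 1), c(n1, n2))
  ncp <- 1 / sqrt(1 / n1 + 1 / n2)
  med_t <- suppressWarnings(qt(0.5, df = n - 2, ncp = ncp))
  analytic <- -log10(2 * pt(-med_t, df = n - 2))
  set.seed(4)
  scores <- replicate(101, score_module(P + rnorm(n), P)$score)
  expect_lt(abs(median(scores) - analytic), 3)
})

test_that("scoring validates its inputs", {
  expect_error(score_module(rep(1, 20), rnorm(20)), "constant module")
  expect_error(score_module(rnorm(20), rep(1, 20)), "constant phenotype")
  P <- rnorm(20)
  expect_error(score_module(rnorm(20), P, covariates = cbind(dup = P)),
               "collinear.*dup|dup")
  expect_error(score_module(rnorm(5), rnorm(5)), "at least 10")
})

test_that("the scorer drops the phenotype from the covariate list", {
  set.seed(5)
  syn <- generate_synthetic(synth_config(
    n_samples = 100, n_features = c(P = 6), n_subpathways = c(P = 2),
    censor_quantile = 0, censored_frac = 0, unknown_frac = 0,
    phenotype = list(name = "gender", type = "binary"), seed = 5))
  x <- log2_transform(syn$data)
  ph <- syn$phenotypes[, setdiff(names(syn$phenotypes), "phenotype")]
  sc <- make_module_scorer(x, ph, phenotype = "gender",
                           covariates = c("age", "gender", "BMI"))
  expect_identical(attr(sc, "covariates"), c("age", "BMI"))
  out <- sc("P::p_met001")
  expect_true(out$p_value > 0 && out$p_value <= 1)
})

test_that("an isolated seed yields a singleton optimal module", {
  net <- mf_network("metabolite", nodes = c("A", "B"))
  sc <- table_scorer(list(A = 1.0, B = 2.0))
  m <- greedy_search(net, "A", sc)
  expect_identical(m$nodes, "A")
  expect_identical(m$status, "optimal")
  expect_error(greedy_search(net, "Z", sc), "not in network")
})

test_that("greedy growth obeys the score and dominance rules on a path", {
  ## path A-B-C; singles 1,1,1; {A,B}=3, {B,C}=3, {A,B,C}=2.5:
  ## from A the pair {A,B} is taken, C is rejected (2.5 < 3)
  net <- mf_network("metabolite", nodes = c("A", "B", "C"),
                    edges = data.frame(from = c("A", "B"), to = c("B", "C"),
                                       pearson_r = 0.5, partial_r = 0.3,
                                       pearson_p = 1e-8, partial_p = 1e-8))
  sc <- table_scorer(list(A = 1, B = 1, C = 1,
                          `A|B` = 3, `B|C` = 3, `A|B|C` = 2.5))
  m <- greedy_search(net, "A", sc)
  expect_identical(m$nodes, c("A", "B"))
  expect_equal(m$score, 3)
  ## a neighbor that beats the module score but not the best single is
  ## rejected too
  sc2 <- table_scorer(list(A = 1, B = 4, C = 1,
                           `A|B` = 3.5, `B|C` = 3, `A|B|C` = 5))
  m2 <- greedy_search(net, "A", sc2)
  expect_identical(m2$nodes, "A")   # 3.5 > 1 but 3.5 < single B = 4
})

test_that("greedy never exceeds the exhaustive optimum on small graphs", {
  for (gs in 1:10) {
    g <- random_graph(sample(4:8, 1), p_edge = 0.45, seed = gs)
    subsets <- connected_subsets(g)
    sc <- stub_scorer(subsets, seed = gs)
    net <- graph_to_network(g)
    best <- vapply(subsets, function(s) sc(s)$score, numeric(1))
    for (seed_node in g$ids) {
      m <- greedy_search(net, seed_node, sc)
      contains_seed <- vapply(subsets, function(s) seed_node %in% s,
                              logical(1))
      expect_lte(m$score, max(best[contains_seed]))
      expect_true(is_connected_subset(m$nodes, g$adj))
      expect_gte(m$score, sc(seed_node)$score)
    }
  }
})

test_that("consolidation merges overlapping optima into disjoint maximal modules", {
  sc <- table_scorer(list(A = 1, B = 1, C = 1, D = 2,
                          `A|B` = 3, `B|C` = 3, `A|B|C` = 4))
  mk <- function(nodes, seed) structure(
    list(nodes = nodes, members = nodes, score = sc(nodes)$score,
         p_value = sc(nodes)$p_value, seeds = seed, status = "optimal"),
    class = "mf_module")
  out <- consolidate(list(mk(c("A", "B"), "A"), mk(c("B", "C"), "B"),
                          mk("D", "D")), sc)
  nodes <- lapply(out, `[[`, "nodes")
  expect_setequal(vapply(nodes, paste, "", collapse = ","),
                  c("A,B,C", "D"))
  expect_true(all(vapply(out, `[[`, "", "status") == "maximal"))
  ## pairwise disjoint
  expect_identical(anyDuplicated(unlist(nodes)), 0L)
  ## identical modules from two seeds merge into one
  out2 <- consolidate(list(mk(c("A", "B"), "A"), mk(c("A", "B"), "B")), sc)
  expect_length(out2, 1)
  expect_setequal(out2[[1]]$seeds, c("A", "B"))
  ## disjoint optima stay separate
  out3 <- consolidate(list(mk("A", "A"), mk("D", "D")), sc)
  expect_length(out3, 2)
})

test_that("significance filtering applies the node-level Bonferroni and dominance rules", {
  sc <- table_scorer(list(M1 = 1, M2 = 1, M3 = 5, M4 = 1,
                          `M1|M2` = -log10(5e-4),
                          `M3|M4` = -log10(1e-7),
                          `M2|M4` = -log10(2e-3)))
  mk <- function(nodes) structure(
    list(nodes = nodes, members = nodes, score = sc(nodes)$score,
         p_value = sc(nodes)$p_value, seeds = nodes[1],
         status = "maximal"), class = "mf_module")
  ## n_nodes = 50 -> threshold 1e-3
  rep <- filter_significant(list(mk(c("M1", "M2")), mk(c("M2", "M4")),
                                 mk(c("M3", "M4"))),
                            n_nodes = 50, alpha = 0.05, scorer = sc)
  expect_equal(rep$bonferroni_threshold, 1e-3)
  kept <- vapply(rep$modules, function(m) paste(m$nodes, collapse = ","),
                 "")
  ## p = 5e-4 kept; p = 2e-3 dropped; {M3,M4} dropped by dominance
  ## (its member M3 alone scores 5 < 7)?  no: 7 > 5, so kept.
  expect_setequal(kept, c("M3,M4", "M1,M2"))
  ## module whose best member outranks it is dropped regardless of p
  sc2 <- table_scorer(list(M1 = 8, M2 = 1, `M1|M2` = 6))
  rep2 <- filter_significant(list(structure(
    list(nodes = c("M1", "M2"), members = c("M1", "M2"), score = 6,
         p_value = 1e-6, seeds = "M1", status = "maximal"),
    class = "mf_module")), n_nodes = 50, scorer = sc2)
  expect_length(rep2$modules, 0)
  ## empty candidate list -> empty report
  rep3 <- filter_significant(list(), n_nodes = 10, scorer = sc)
  expect_length(rep3$modules, 0)
  expect_error(filter_significant(list(), 0, scorer = sc), "positive")
})

test_that("a planted sparse module is recovered end to end", {
  res <- run_planted_search(seed = 1)
  report <- res$report
  expect_gte(length(report$modules), 1)
  hit <- vapply(report$modules, function(m)
    length(intersect(m$nodes, planted_nodes)) >= 3, logical(1))
  expect_true(any(hit))
  ## every reported module dominates its members and is connected
  sc <- make_module_scorer(res$x, res$ph, "igf1", level = "metabolite",
                           annotations = res$syn$annotations)
  adj <- lapply(setNames(res$net$nodes, res$net$nodes), function(nd)
    unique(c(res$net$edges$to[res$net$edges$from == nd],
             res$net$edges$from[res$net$edges$to == nd])))
  for (m in report$modules) {
    singles <- vapply(m$nodes, function(u) sc(u)$score, numeric(1))
    expect_gt(m$score, max(singles))
    expect_lt(m$p_value, report$bonferroni_threshold)
    expect_true(is_connected_subset(m$nodes, adj))
  }
  ## maximal modules pairwise disjoint
  expect_identical(anyDuplicated(unlist(lapply(report$modules,
                                               `[[`, "nodes"))), 0L)
})

test_that("a permuted phenotype yields no modules", {
  res <- run_planted_search(seed = 1, permute = TRUE)
  expect_length(res$report$modules, 0)
})

test_that("dense phenotypes surface more modules at the metabolite level", {
  ## effects on half the metabolites: the fine-grained network should
  ## yield at least as many modules as the sub-pathway network
  cfg <- synth_config(
    n_samples = 906, n_features = c(P = 40), n_subpathways = c(P = 10),
    loading = 0.5, n_rundays = 1, runday_log2_sd = 0,
    dilution_log2_sd = c(P = 0), censor_quantile = 0, censored_frac = 0,
    unknown_frac = 0, phenotype = list(name = "gender", type = "binary"),
    planted_modules = list(list(features = sprintf("p_met%03d", 1:20),
                                beta = 0.12)),
    seed = 31)
  syn <- generate_synthetic(cfg)
  x <- log2_transform(syn$data)
  ph <- syn$phenotypes[, setdiff(names(syn$phenotypes), "phenotype")]
  map <- suppressWarnings(build_hierarchical_map(x, syn$annotations))
  rep_met <- run_module_identification(map, x, ph, phenotype = "gender",
                                       level = "metabolite")
  rep_sub <- run_module_identification(map, x, ph, phenotype = "gender",
                                       level = "sub_pathway")
  expect_gte(length(rep_met$modules), 1)
  expect_gte(length(rep_met$modules), length(rep_sub$modules))
})

test_that("module reports print and tabulate coherently", {
  res <- run_planted_search(seed = 2)
  tab <- module_report_table(res$report)
  expect_identical(nrow(tab), length(res$report$modules))
  if (nrow(tab) > 0) {
    expect_true(all(tab$p_value < res$report$bonferroni_threshold))
    expect_equal(tab$score, -log10(tab$p_value), tolerance = 1e-8)
  }
  expect_output(print(res$report), "module_report")
})
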
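test_that("entry_screen equals the per-gene brute-force check", {
  cfg <- screen_config()
  sim <- simulate_expression(300, cfg, frac_affected = 0.1,
                             log2_effect = 1.5, cv = 0.15, seed = 21)
  res <- entry_screen(sim$expr, cfg)
  # independent brute force: compare the focal mean against every
  # comparison-condition mean, gene by gene
  comps <- c("ptr", "mmu", "cja", "vec")
  for (g in rownames(sim$expr$values)) {
    fm <- mean(condition_values(sim$expr, "hsa")[g, ])
    cms <- sapply(comps, function(cc) mean(condition_values(sim$expr, cc)[g, ]))
    if (all(fm > cms)) {
      expect_equal(res$direction[res$gene == g], "up")
    } else if (all(fm < cms)) {
      expect_equal(res$direction[res$gene == g], "down")
    } else {
      expect_false(g %in% res$gene)
    }
  }
})

test_that("twofold filter is boundary-inclusive on |log2 fold|", {
  cfg <- screen_config()
  fake_stats <- list(
    strong = list(min_fold_change = 25.657),
    weak = list(min_fold_change = 0.572),
    boundary_up = list(min_fold_change = 2.0),
    boundary_down = list(min_fold_change = 0.5),
    undefined = list(min_fold_change = NA_real_))
  kept <- twofold_filter(names(fake_stats), fake_stats, cfg)
  expect_setequal(kept, c("strong", "boundary_up", "boundary_down"))
})

test_that("classify applies the reproduced / new_candidate / rejected rules", {
  cfg <- screen_config()
  sim <- simulate_expression(400, cfg, frac_affected = 0.08,
                             log2_effect = 2.5, cv = 0.10, seed = 33)
  cand <- entry_screen(sim$expr, cfg)
  st <- screen_stats(sim$expr, cfg)
  planted <- sim$truth$gene[sim$truth$planted_direction != "none"]
  # plant list membership: half the planted genes are "previously reported"
  in_ref <- planted[seq_len(floor(length(planted) / 2))]
  refs <- list(studyA = in_ref)
  ann <- data.frame(gene = rownames(sim$expr$values),
                    protein_coding = TRUE, brain_expressed = TRUE)
  res <- classify(cand, st, refs, ann, cfg)
  expect_true(all(res$category %in% c("reproduced", "new_candidate",
                                      "rejected")))
  # rule checks against the planted memberships
  rep_rows <- res[res$category == "reproduced", ]
  expect_true(all(rep_rows$in_reference_lists != ""))
  expect_true(all(rep_rows$fdr < cfg$alpha))
  new_rows <- res[res$category == "new_candidate", ]
  expect_true(all(new_rows$in_reference_lists == ""))
  expect_true(all(new_rows$passes_twofold))
  # every listed planted gene that passed entry with significant FDR is
  # reproduced, never new_candidate
  listed <- res[res$gene %in% in_ref & res$fdr < cfg$alpha, ]
  expect_true(all(listed$category == "reproduced"))
  # a gene absent from annotations cannot be a new candidate
  res2 <- classify(cand, st, refs,
                   data.frame(gene = character(), protein_coding = logical(),
                              brain_expressed = logical()), cfg)
  expect_false(any(res2$category == "new_candidate"))
})

test_that("validate reproduces the printed panel statistics", {
  cfg <- screen_config()
  v <- validate(qpcr_fixture(), cfg)
  tab <- comparison_table(v$stats)
  row <- function(g) tab[tab$gene == g, ]
  expect_equal(row("BACE2")$r_effect, 0.735, tolerance = 0.001)
  expect_equal(row("BACE2")$min_fold_change, 0.355, tolerance = 0.001)
  expect_equal(row("SEBOX")$r_effect, 0.998, tolerance = 0.001)
  expect_equal(row("SEBOX")$min_fold_change, 25.657, tolerance = 0.001)
  expect_equal(row("NURR1")$r_effect, 0.743, tolerance = 0.001)
  expect_equal(row("NURR1")$power, 0.745, tolerance = 0.005)
  expect_equal(row("GABRE")$r_effect, 0.933, tolerance = 0.001)
  # the full printed-panel chain: r to +/-0.001 and power to +/-0.005
  printed <- data.frame(
    gene = c("BACE2", "DCDC2", "CDH4", "FOXL1", "GABRE", "MSN", "MYH8",
             "MYH13", "NURR1", "PHOX2B", "PTPRQ", "SEBOX", "TMEM200A"),
    r = c(0.735, 0.767, 0.808, 0.897, 0.933, 0.931, 0.923, 0.922, 0.743,
          0.589, 0.556, 0.998, 0.731),
    power = c(0.725, 0.803, 0.895, 0.997, 1.000, 1.000, 1.000, 1.000, 0.745,
              0.411, 0.357, 1.000, 0.715))
  for (i in seq_len(nrow(printed))) {
    expect_equal(row(printed$gene[i])$r_effect, printed$r[i],
                 tolerance = 0.0011)
    expect_equal(row(printed$gene[i])$power, printed$power[i],
                 tolerance = 0.0051)
  }
  # discordance flagging: under the Student variant NURR1 misses the
  # panel-family FDR threshold but keeps its large r -> flagged, not merged
  vs <- validate(qpcr_fixture(), cfg, variant = "student")
  expect_equal(vs$verdicts$verdict[vs$verdicts$gene == "NURR1"],
               "large_effect_ns")
  # identical values in all conditions -> ns with r = 0
  flat <- data.frame(gene = "F", condition = rep(c("hsa", "ptr"), each = 2),
                     bio_rep = rep(c("I", "II"), 2), value = 1)
  vf <- validate(flat, cfg)
  expect_equal(vf$stats$F$r_effect, 0)
  expect_equal(vf$verdicts$verdict, "ns")
})

test_that("reduced-sample re-analysis recomputes r with reduced M", {
  cfg <- screen_config()
  red <- reduced_sample_reanalysis(qpcr_fixture(), "cja", cfg)
  tab <- comparison_table(red$stats)
  expect_equal(tab[tab$gene == "BACE2", "M"], 4)
  expect_equal(tab[tab$gene == "BACE2", "r_effect"], 0.986,
               tolerance = 0.001)
  expect_equal(tab[tab$gene == "NURR1", "min_fold_change"], 0.044,
               tolerance = 0.001)
  expect_equal(tab[tab$gene == "NURR1", "r_effect"], 0.943,
               tolerance = 0.001)
  # empty drop set is identical to validate
  full <- validate(qpcr_fixture(), cfg)
  red0 <- reduced_sample_reanalysis(qpcr_fixture(), character(), cfg)
  expect_identical(red0, full)
  expect_error(reduced_sample_reanalysis(qpcr_fixture(),
                                         c("ptr", "mmu", "cja"), cfg),
               "every comparison")
})

test_that("densitometry panel reproduces the printed protein statistics", {
  cfg <- screen_config()
  v <- validate(densitometry_fixture(), cfg)
  tab <- comparison_table(v$stats)
  expect_equal(tab[tab$gene == "CDH4", "r_effect"], 0.861, tolerance = 0.001)
  expect_equal(tab[tab$gene == "CDH4", "power"], 0.976, tolerance = 0.005)
  expect_equal(tab[tab$gene == "MSN", "r_effect"], 0.775, tolerance = 0.001)
  expect_equal(tab[tab$gene == "MSN", "power"], 0.822, tolerance = 0.005)
  # BACE2 is measured without the cja condition: M = 4
  expect_equal(tab[tab$gene == "BACE2", "M"], 4)
  expect_equal(tab[tab$gene == "BACE2", "r_effect"], 0.900, tolerance = 0.001)
  expect_equal(tab[tab$gene == "BACE2", "power"], 0.958, tolerance = 0.005)
})

test_that("compare_dnds: enumeration example, identity, selection note", {
  # identical columns
  same <- data.frame(gene = letters[1:4], dnds_pair_a = c(.1, .2, .3, .4),
                     dnds_pair_b = c(.1, .2, .3, .4))
  res <- compare_dnds(same)
  expect_gte(res$mwu$p_two_sided, 0.9)
  expect_equal(res$mean_a, res$mean_b)
  expect_equal(res$note, "purifying selection")
  # (0.1,0.2,0.3) vs (0.4,0.5,0.6): two-sided exact p = 0.1 by enumeration
  sep <- data.frame(gene = letters[1:3], dnds_pair_a = c(.1, .2, .3),
                    dnds_pair_b = c(.4, .5, .6))
  expect_equal(compare_dnds(sep)$mwu$p_two_sided, 0.1)
  # values above 1 suppress the purifying-selection note
  mixed <- data.frame(gene = letters[1:3], dnds_pair_a = c(.1, .2, 1.3),
                      dnds_pair_b = c(.4, .5, .6))
  expect_true(is.na(compare_dnds(mixed)$note))
})

test_that("planted-truth recovery and type-I behaviour (scaled simulation)", {
  cfg <- screen_config()
  # planted log2 effect 1.5 at CV 10%: >= 95% pass entry + twofold
  sim <- simulate_expression(500, cfg, frac_affected = 0.1,
                             log2_effect = 1.5, cv = 0.10, seed = 77)
  cand <- entry_screen(sim$expr, cfg)
  st <- screen_stats(sim$expr, cfg, genes = cand$gene)
  passed <- twofold_filter(cand$gene, st, cfg)
  planted <- sim$truth$gene[sim$truth$planted_direction != "none"]
  expect_gte(mean(planted %in% passed), 0.95)
  # zero planted effect: FDR < 0.05 fraction <= 0.05 within binomial error
  # over repeated seeds (scaled: 5 seeds x 200 genes in-suite)
  fprs <- sapply(1:5, function(s) {
    sim0 <- simulate_expression(200, cfg, frac_affected = 0, cv = 0.15,
                                seed = 100 + s)
    st0 <- screen_stats(sim0$expr, cfg)
    mean(comparison_table(st0)$fdr < 0.05)
  })
  n_total <- 5 * 200
  expect_lte(mean(fprs), 0.05 + 3 * sqrt(0.05 * 0.95 / n_total))
})
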
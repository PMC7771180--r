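fun_rules <- function(...) {
  rbind(data.frame(taxon_key = "Araneae", rank = "order", category = "non_volant"),
        data.frame(taxon_key = "Diptera", rank = "order",
                   category = "nocturnally_volant"),
        ...)
}

test_that("functional classification picks the most specific rule", {
  tax <- data.frame(bin_id = c("b1", "b2", "b3", "b4"),
                    order_name = c("Araneae", "Diptera", "Diptera", "Mantodea"),
                    family_name = c(NA, "Syrphidae", "Culicidae", NA),
                    species_name = NA_character_)
  rules <- fun_rules(data.frame(taxon_key = "Syrphidae", rank = "family",
                                category = "not_actively_volant"))
  cl <- classify_bins(tax, rules)
  expect_equal(unname(cl["b1"]), "non_volant")          # wingless order
  expect_equal(unname(cl["b2"]), "not_actively_volant") # family overrides order
  expect_equal(unname(cl["b3"]), "nocturnally_volant")  # order fallback
  expect_equal(unname(cl["b4"]), "unclassified")        # no rule

  bad <- rbind(fun_rules(),
               data.frame(taxon_key = "Araneae", rank = "order",
                          category = "nocturnally_volant"))
  expect_error(classify_bins(tax, bad), "conflicting")
})

test_that("per-sample not-nocturnally-volant fraction is count-based", {
  tax <- data.frame(bin_id = paste0("b", 1:5),
                    order_name = c("Araneae", "Araneae", "Diptera", "Diptera",
                                   "Mantodea"),
                    family_name = NA_character_, species_name = NA_character_)
  cl <- classify_bins(tax, fun_rules())
  comp <- data.frame(sample_id = "s", bin_id = paste0("b", 1:4), reads = c(1, 1, 99, 99))
  fd <- functional_diet(comp, cl)
  expect_equal(fd$per_sample$pct_not_nocturnally_volant, 0.5)  # 2 of 4, not read-weighted

  comp2 <- data.frame(sample_id = "s", bin_id = c("b3", "b4"), reads = 1)
  expect_equal(functional_diet(comp2, cl)$per_sample$pct_not_nocturnally_volant, 0)

  # unclassified BINs are excluded from the denominator
  comp3 <- data.frame(sample_id = "s", bin_id = c("b1", "b5"), reads = 1)
  fd3 <- functional_diet(comp3, cl)
  expect_equal(fd3$per_sample$n_classified, 1L)
  expect_equal(fd3$per_sample$pct_not_nocturnally_volant, 1)
  expect_equal(sum(fd3$composition$proportion), 1)
})

test_that("functional wPOO recovers a planted category mixture", {
  mix <- c(non_volant = 0.2, not_actively_volant = 0.45,
           nocturnally_volant = 0.35)
  args <- c(list(n_sites = c(allopatric_A = 1L, allopatric_B = 0L,
                             allotopic_A = 0L, allotopic_B = 0L, syntopic = 0L),
                 samples_per_site = 80L, n_bins_total = 120L, pool_size = 40L,
                 reads_per_run_mean = 800, sweep_samples_per_site = 0L,
                 category_mixture = mix, seed = 30),
            noiseless_args())
  st <- generate_study(do.call(generator_config, args))
  comp <- plain_composition(st$reads)
  comp <- comp[comp$sample_id %in%
                 st$meta$sample_id[st$meta$sample_type == "dropping"], ]
  cl <- classify_bins(st$taxonomy, st$functional)
  fd <- functional_diet(comp, cl)
  got <- setNames(fd$composition$proportion, fd$composition$item)
  expect_true(all(abs(got[names(mix)] - mix) < 0.05))
})

test_that("representativeness gate is inclusive at 20%", {
  diet <- data.frame(sample_id = "d1", bin_id = paste0("b", 1:10), reads = 1)
  sweep_hit <- data.frame(sample_id = "w1", bin_id = c("b1", "b2"), reads = 1)
  meta <- rbind(meta_row("d1", site_id = "s1"),
                meta_row("w1", "sweeping", site_id = "s1"),
                meta_row("d2", site_id = "s2"),
                meta_row("w2", "sweeping", site_id = "s2"))
  out <- representativeness_filter(diet, sweep_hit, meta)
  expect_equal(out$fraction, 0.2)
  expect_true(out$retained)           # exactly 20% retained

  sweep_low <- data.frame(sample_id = "w1",
                          bin_id = c("b1", paste0("x", 1:5)), reads = 1)
  out2 <- representativeness_filter(diet, sweep_low, meta)
  expect_equal(out2$fraction, 0.1)
  expect_false(out2$retained)

  # sweep superset of the diet
  sweep_all <- data.frame(sample_id = "w1", bin_id = paste0("b", 1:12), reads = 1)
  expect_equal(representativeness_filter(diet, sweep_all, meta)$fraction, 1)

  diet2 <- rbind(diet, data.frame(sample_id = "d2", bin_id = "b1", reads = 1))
  expect_warning(representativeness_filter(diet2, sweep_hit, meta),
                 "without sweep data")
})

test_that("representativeness grows with sweep coverage", {
  frac_at <- function(cov) {
    st <- generate_study(small_config(seed = 44, sweep_coverage = cov))
    f <- filter_study(st$reads, st$meta)
    ids <- split(st$meta$sample_id, st$meta$sample_type)
    out <- suppressWarnings(representativeness_filter(
      f$composition[f$composition$sample_id %in% ids$dropping, ],
      f$composition[f$composition$sample_id %in% ids$sweeping, ],
      st$meta))
    mean(out$fraction)
  }
  expect_lt(frac_at(0.15), frac_at(0.8))
})

test_that("selection is the per-item simplex difference and sums to zero", {
  d <- data.frame(unit_id = "s", item = c("Lepidoptera", "Diptera"),
                  proportion = c(0.6, 0.4))
  a <- data.frame(unit_id = "s", item = c("Lepidoptera", "Diptera"),
                  proportion = c(0.4, 0.6))
  rows <- selection_index(d, a, "site1")
  v <- setNames(rows$selection, rows$item)
  expect_equal(unname(v[c("Lepidoptera", "Diptera")]), c(0.2, -0.2))
  expect_equal(sum(rows$selection), 0)

  same <- selection_index(d, d, "site1")
  expect_true(all(same$selection == 0))
})

test_that("selection summary flags by quartile position", {
  rows <- do.call(rbind, lapply(1:5, function(i)
    data.frame(site_id = paste0("s", i), item = "Lepidoptera",
               diet_wpoo = NA, availability_wpoo = NA,
               selection = 0.1 * i)))
  s <- selection_summary(rows, n_boot = 200, seed = 1)
  expect_equal(s$flag, "over")
  expect_true(s$ci_lo > 0)

  rows$selection <- -rows$selection
  expect_equal(selection_summary(rows, n_boot = 200, seed = 1)$flag, "under")

  rows3 <- data.frame(site_id = paste0("s", 1:3), item = "x",
                      diet_wpoo = NA, availability_wpoo = NA,
                      selection = c(-0.1, 0, 0.1))
  expect_equal(selection_summary(rows3, n_boot = 200, seed = 1)$flag, "neutral")

  rows2 <- rows3[1:2, ]
  expect_warning(s2 <- selection_summary(rows2, n_boot = 50), "fewer than 3")
  expect_true(is.na(s2$ci_lo))
})

test_that("the full selection pipeline respects the gate and zero-sum", {
  st <- generate_study(small_config(seed = 50, sweep_coverage = 0.8))
  f <- filter_study(st$reads, st$meta)
  ids <- split(st$meta$sample_id, st$meta$sample_type)
  ps <- suppressWarnings(prey_selection(
    f$composition[f$composition$sample_id %in% ids$dropping, ],
    f$composition[f$composition$sample_id %in% ids$sweeping, ],
    st$meta, taxonomy = st$taxonomy, n_boot = 200, seed = 3))
  sums <- tapply(ps$selection$selection, ps$selection$site_id, sum)
  expect_true(all(abs(sums) < 1e-9))
  expect_true(all(ps$selection$selection >= -1 & ps$selection$selection <= 1))
  expect_true(all(ps$representativeness$fraction[
    ps$representativeness$retained] >= 0.2))
})
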
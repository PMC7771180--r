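test_that("low-read removal keeps the boundary and logs removals", {
  tab <- rr("d1", "A", 1, c("b1", "b2", "b3"), c(1, 2, 10))
  out <- remove_low_read_bins(tab, 2)
  expect_setequal(out$reads$bin_id, c("b2", "b3"))  # reads = 2 retained
  expect_equal(out$audit$rule, "singleton")
  expect_equal(out$audit$bin_id, "b1")

  expect_identical(remove_low_read_bins(tab, 1)$reads, tab)  # identity
  expect_error(remove_low_read_bins(tab, 0), "min_reads")

  # idempotent
  twice <- remove_low_read_bins(out$reads, 2)
  expect_identical(twice$reads, out$reads)
  expect_equal(nrow(twice$audit), 0L)
})

blank_fixture <- function(sample_reads) {
  reads <- rbind(rr("blk", "A", 1, "b1", 5),
                 rr("d1", "A", 1, c("b1", "b2"), c(sample_reads, 30)))
  meta <- rbind(meta_row("blk", "blank_extraction"), meta_row("d1"))
  list(reads = reads, meta = meta)
}

test_that("blank contamination rule is strict at the 10x boundary", {
  fx <- blank_fixture(49)       # 49 < 10 x 5 -> removed
  out <- filter_blank_contamination(fx$reads, fx$meta)
  expect_false(any(out$reads$sample_id == "d1" & out$reads$bin_id == "b1"))
  expect_equal(out$audit$blank_reads, 5)

  fx <- blank_fixture(50)       # 50 = 10 x 5 -> retained
  out <- filter_blank_contamination(fx$reads, fx$meta)
  expect_true(any(out$reads$sample_id == "d1" & out$reads$bin_id == "b1"))

  # BINs absent from all blanks are never touched
  expect_true(any(out$reads$bin_id == "b2"))

  # idempotent
  again <- filter_blank_contamination(out$reads, fx$meta)
  expect_identical(again$reads, out$reads)
})

test_that("blank scoping restricts removal to the blank's batch", {
  reads <- rbind(rr("blk", "A", 1, "b1", 5),
                 rr("d1", "A", 1, "b1", 20),   # same batch, 20 < 50
                 rr("d2", "A", 1, "b1", 20))   # other batch
  meta <- rbind(meta_row("blk", "blank_extraction", extraction_batch_id = "b1"),
                meta_row("d1", extraction_batch_id = "b1"),
                meta_row("d2", extraction_batch_id = "b2"))
  out <- filter_blank_contamination(reads, meta, scope = "batch")
  expect_false("d1" %in% out$reads$sample_id[out$reads$bin_id == "b1"])
  expect_true("d2" %in% out$reads$sample_id[out$reads$bin_id == "b1"])
  outg <- filter_blank_contamination(reads, meta, scope = "global")
  expect_false("d2" %in% outg$reads$sample_id[outg$reads$bin_id == "b1"])

  expect_warning(
    filter_blank_contamination(rr("d1", "A", 1, "b1", 5), meta_row("d1")),
    "no blanks")
})

test_that("planted contaminants are removed; clean BINs are untouched", {
  st <- generate_study(small_config(seed = 21))
  f1 <- remove_low_read_bins(st$reads, 2)
  f2 <- filter_blank_contamination(f1$reads, st$meta)
  expect_true(all(f2$audit$bin_id %in% st$truth$contaminant_bins))

  # occurrences below 10x the blank level are removed at >= 95%
  blank_ids <- st$meta$sample_id[grepl("^blank", st$meta$sample_type)]
  is_blank <- f1$reads$sample_id %in% blank_ids
  rb <- tapply(f1$reads$reads[is_blank], f1$reads$bin_id[is_blank], max)
  cont <- !is_blank & f1$reads$bin_id %in% st$truth$contaminant_bins
  low <- cont & f1$reads$reads < 10 * rb[f1$reads$bin_id]
  kept_key <- paste(f2$reads$sample_id, f2$reads$primer_id,
                    f2$reads$replicate_id, f2$reads$bin_id)
  all_key <- paste(f1$reads$sample_id, f1$reads$primer_id,
                   f1$reads$replicate_id, f1$reads$bin_id)
  expect_gte(mean(!(all_key[low] %in% kept_key)), 0.95)
})

test_that("additive combination unions replicates and sums reads", {
  tab <- rbind(rr("d1", "A", 1, "b1", 5), rr("d1", "A", 2, "b2", 7))
  comp <- combine_replicates_additive(tab)
  expect_setequal(comp$bin_id, c("b1", "b2"))

  tab2 <- rbind(rr("d1", "A", 1, "b1", 5), rr("d1", "A", 2, "b1", 5))
  comp2 <- combine_replicates_additive(tab2)
  expect_equal(comp2$reads, 10)
})

test_that("conservative combination intersects replicates and gates run totals", {
  tab <- rbind(full_runs("ok", c("b1", "b2"), c(100, 60)),
               rr("low", "A", 1, "b1", 150), rr("low", "A", 2, "b1", 150),
               rr("low", "B", 1, "b1", 150), rr("low", "B", 2, "b1", 99))
  out <- combine_replicates_conservative(tab, 100)
  expect_equal(out$dropped_samples, "low")  # one run total = 99 <= 100
  expect_setequal(unique(out$composition$sample_id), "ok")

  # boundary: a run with exactly 100 reads drops the sample (> 100 required)
  tab2 <- rbind(full_runs("x", "b1", 100))
  expect_equal(combine_replicates_conservative(tab2, 100)$dropped_samples, "x")

  # BIN in one replicate only is excluded; in both replicates of one primer
  # it is retained via the primer union
  tab3 <- rbind(full_runs("s", "b0", 200),
                rr("s", "A", 1, "b_once", 50),
                rr("s", "A", 1, "b_pairA", 50), rr("s", "A", 2, "b_pairA", 50))
  out3 <- combine_replicates_conservative(tab3, 100)
  merged <- merge_primers(out3$composition)
  expect_false("b_once" %in% merged$bin_id)
  expect_true("b_pairA" %in% merged$bin_id)

  # missing runs -> dropped
  tab4 <- rbind(rr("m", "A", 1, "b1", 500), rr("m", "A", 2, "b1", 500),
                full_runs("ok2", "b1", 500))
  expect_true("m" %in% combine_replicates_conservative(tab4, 100)$dropped_samples)
})

test_that("primer union obeys inclusion-exclusion on random fixtures", {
  comp <- rbind(data.frame(sample_id = "s", primer_id = "A",
                           bin_id = c("b1", "b2"), reads = 1),
                data.frame(sample_id = "s", primer_id = "B",
                           bin_id = c("b2", "b3"), reads = 1))
  expect_setequal(merge_primers(comp)$bin_id, c("b1", "b2", "b3"))

  set.seed(31)
  for (i in 1:20) {
    a <- sample(paste0("b", 1:15), sample(1:10, 1))
    b <- sample(paste0("b", 1:15), sample(1:10, 1))
    comp <- rbind(data.frame(sample_id = "s", primer_id = "A", bin_id = a, reads = 1),
                  data.frame(sample_id = "s", primer_id = "B", bin_id = b, reads = 1))
    m <- merge_primers(comp)
    expect_equal(nrow(m), length(a) + length(b) - length(intersect(a, b)))
  }
})

test_that("primer recovery proportions sum to one per order", {
  st <- generate_study(small_config(seed = 12))
  f <- filter_study(st$reads, st$meta)
  pr <- primer_recovery_summary(f$per_primer, st$taxonomy)
  expect_true(all(abs(pr$prop_only_A + pr$prop_only_B + pr$prop_both - 1) < 1e-12))
  expect_equal(pr$n_only_A + pr$n_only_B + pr$n_both,
               as.vector(table(st$taxonomy$order_name[
                 match(unique(f$per_primer$bin_id), st$taxonomy$bin_id)])[
                   pr$order_name]))
})

test_that("threshold calibration scores Jaccard correctly and breaks ties low", {
  # single sweep sample: molecular {Diptera, Araneae}, morphological {Diptera}
  reads <- rr("w1", "A", 1, c("b1", "b2"), c(10, 10))
  tax <- tiny_taxonomy(c("b1", "b2"), c("Diptera", "Araneae"))
  morph <- data.frame(sweep_sample_id = "w1", order_name = "Diptera",
                      individuals = 5)
  cal <- calibrate_min_read_threshold(reads, tax, morph)
  expect_true(all(cal$scores == 0.5))
  expect_equal(cal$chosen, 1L)  # perfect tie -> smallest threshold

  # agreement at every threshold -> all scores 1, chosen = 1
  morph2 <- data.frame(sweep_sample_id = "w1",
                       order_name = c("Diptera", "Araneae"), individuals = 1)
  cal2 <- calibrate_min_read_threshold(reads, tax, morph2)
  expect_true(all(cal2$scores == 1))
  expect_equal(cal2$chosen, 1L)

  expect_error(
    calibrate_min_read_threshold(reads, tax,
                                 data.frame(sweep_sample_id = "other",
                                            order_name = "Diptera",
                                            individuals = 1)),
    "no samples shared")
})

test_that("calibration recovers a planted optimum of two reads", {
  st <- generate_study(small_config(seed = 15))
  sweep_ids <- st$meta$sample_id[st$meta$sample_type == "sweeping"]
  cal <- calibrate_min_read_threshold(
    st$reads[st$reads$sample_id %in% sweep_ids, ], st$taxonomy, st$morph)
  expect_equal(cal$chosen, 2L)
  expect_lt(cal$scores[["1"]], cal$scores[["2"]])
})
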
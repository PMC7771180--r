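# shared fixtures and independent oracles

rr <- function(sample, primer, rep, bin, reads) {
  data.frame(sample_id = sample, primer_id = primer, replicate_id = as.character(rep),
             bin_id = bin, reads = reads, stringsAsFactors = FALSE)
}

# a full 2x2 run layout for one sample with the same BIN set in every run
full_runs <- function(sample, bins, reads) {
  do.call(rbind, lapply(c("A", "B"), function(p)
    do.call(rbind, lapply(c("1", "2"), function(r) rr(sample, p, r, bins, reads)))))
}

meta_row <- function(sample_id, sample_type = "dropping",
                     bat_species = "escalerai", site_id = "s1",
                     broad_class = "allopatric", fine_class = NA_character_,
                     extraction_batch_id = "b1", sequencing_run_id = "run1") {
  data.frame(sample_id = sample_id, sample_type = sample_type,
             bat_species = if (grepl("^blank", sample_type)) NA_character_ else bat_species,
             site_id = site_id, region_id = "r1", broad_class = broad_class,
             fine_class = fine_class, extraction_batch_id = extraction_batch_id,
             sequencing_run_id = sequencing_run_id,
             longitude = NA_real_, latitude = NA_real_, stringsAsFactors = FALSE)
}

tiny_taxonomy <- function(bins, orders) {
  data.frame(bin_id = bins, order_name = orders,
             family_name = NA_character_, species_name = NA_character_,
             stringsAsFactors = FALSE)
}

# small, fast generator setups
small_config <- function(...) {
  generator_config(n_sites = c(allopatric_A = 2L, allopatric_B = 2L,
                               allotopic_A = 2L, allotopic_B = 2L,
                               syntopic = 2L),
                   samples_per_site = 3L, n_bins_total = 120L, pool_size = 40L,
                   reads_per_run_mean = 800, sweep_reads_mean = 1500,
                   mean_items_sweep = 15, ...)
}

noiseless_args <- function() {
  list(detection_bias = list(), blind_orders = character(0),
       blind_detection = 1, dropout = 0, n_contaminants = 0L,
       carry_prob = 0, n_noise_singletons = 0L)
}

# additive replicate combination + primer union without blank handling
plain_composition <- function(reads) merge_primers(combine_replicates_additive(reads))

## independent oracles ---------------------------------------------------

oracle_pianka <- function(p, q) {
  num <- 0; s1 <- 0; s2 <- 0
  for (i in seq_along(p)) {
    num <- num + p[i] * q[i]
    s1 <- s1 + p[i]^2
    s2 <- s2 + q[i]^2
  }
  num / sqrt(s1 * s2)
}

oracle_jaccard <- function(a, b) 1 - length(intersect(a, b)) / length(union(a, b))

oracle_levins <- function(p, n) {
  B <- 1 / sum(p * p)
  list(B = B, B_A = (B - 1) / (n - 1))
}

# exact ANOSIM R by explicit rank arithmetic on all object pairs
oracle_anosim_R <- function(d, groups) {
  m <- as.matrix(d)
  n <- nrow(m)
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  dv <- m[pairs]
  rk <- rank(dv)  # average ranks on ties
  within <- groups[pairs[, 1]] == groups[pairs[, 2]]
  (mean(rk[!within]) - mean(rk[within])) / (n * (n - 1) / 4)
}

oracle_haversine_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * 6371.0088 * asin(pmin(1, sqrt(a)))
}

# brute-force per-sample wPOO: average of item-share vectors
oracle_wpoo <- function(sets) {
  items <- sort(unique(unlist(sets)))
  shares <- sapply(sets, function(s) {
    v <- setNames(numeric(length(items)), items)
    v[s] <- 1 / length(s)
    v
  })
  rowMeans(shares)
}
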
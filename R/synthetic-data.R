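DIET_ORDERS <- c(Lepidoptera = 0.24, Diptera = 0.24, Araneae = 0.17,
                 Hemiptera = 0.10, Coleoptera = 0.08, Orthoptera = 0.06,
                 Neuroptera = 0.04, Trichoptera = 0.04, Blattodea = 0.02,
                 Ephemeroptera = 0.01)

ORDER_CATEGORY <- c(
  Araneae = "non_volant", Isopoda = "non_volant", Opiliones = "non_volant",
  Hemiptera = "not_actively_volant", Orthoptera = "not_actively_volant",
  Coleoptera = "not_actively_volant", Blattodea = "not_actively_volant",
  Psocodea = "not_actively_volant", Thysanoptera = "not_actively_volant",
  Lepidoptera = "nocturnally_volant", Diptera = "nocturnally_volant",
  Neuroptera = "nocturnally_volant", Trichoptera = "nocturnally_volant",
  Ephemeroptera = "nocturnally_volant", Hymenoptera = "nocturnally_volant")

NOISE_ORDERS <- c("Psocodea", "Thysanoptera")

#' Configuration for the synthetic-study generator
#'
#' Builds a validated configuration emulating the sampling design of a
#' two-species metabarcoding diet study: two allopatric regions (one per
#' species), and a sympatric region holding allotopic sites (one species
#' each) and syntopic sites (both species), each site contributing several
#' fecal ("dropping") samples sequenced in 2 primers x 2 PCR replicates,
#' sweep-net availability samples, morphological order counts, and
#' extraction/sequencing blanks carrying planted contaminant BINs.
#'
#' @param n_sites named integer vector: sites per stratum
#'   (`allopatric_A`, `allopatric_B`, `allotopic_A`, `allotopic_B`,
#'   `syntopic`; species A = *M. escalerai*, B = *M. crypticus*).
#' @param samples_per_site dropping samples per site and species.
#' @param n_bins_total size of the BIN universe.
#' @param pool_size prey-pool size per species.
#' @param pool_overlap fraction of pool BINs shared between species.
#' @param pool_conc Dirichlet(-like) gamma shape for prey "abundance"
#'   weights; species use shared prey in proportion to a common abundance
#'   draw, so identical pools imply identical utilization.
#' @param syntopic_shift in `[0, 1]`: divergence applied only in syntopic
#'   sites — each species down-weights its half of the shared pool by
#'   `1 - syntopic_shift`.
#' @param mean_items expected prey items per dropping sample (Poisson
#'   intensity split over the pool by weight).
#' @param reads_per_run_mean,reads_dispersion negative-binomial read depth
#'   per run.
#' @param detection_bias named list per primer of named per-order detection
#'   probabilities (default: mild, realistic primer bias).
#' @param blind_orders orders present in availability but nearly invisible
#'   to the molecular assay; `blind_detection` their detection probability.
#' @param blind_detection see `blind_orders`.
#' @param dropout probability a PCR run fails entirely.
#' @param n_contaminants,blank_mean_reads,carry_prob,carry_mean planted
#'   contamination: number of contaminant BINs, expected blank reads per
#'   contaminant, per-run carry-over probability into real samples, and
#'   the (geometric) mean carry-over read count.
#' @param sweep_samples_per_site sweep samples per site.
#' @param sweep_coverage fraction of the site's diet-pool BINs present in
#'   its availability composition.
#' @param mean_items_sweep expected items per sweep sample.
#' @param sweep_reads_mean read depth for sweep runs.
#' @param sweep_extra_bins,sweep_extra_mass availability-only BINs and the
#'   probability mass they (plus blind-order BINs) carry.
#' @param n_noise_singletons 1-read noise BINs (from orders foreign to the
#'   arthropod community) injected per sweep run.
#' @param morph_mean_individuals mean morphologically identified
#'   individuals per sweep sample.
#' @param batch_size samples per extraction batch (one extraction blank
#'   each; a single sequencing run with one sequencing blank).
#' @param category_mixture optional proportions over the three volancy
#'   categories; when set, pool BINs are allocated to categories in these
#'   proportions with uniform weights, so the expected functional wPOO
#'   equals the mixture.
#' @param selection_shift optional `list(order =, factor =)`: multiply the
#'   availability weight of one order by `factor` (diet unchanged), planting
#'   prey selection.
#' @param seed integer master seed; per-sample substreams are derived from
#'   it so adding samples does not perturb existing ones.
#' @return validated config list (class `"trophiq_config"`).
#' @export
generator_config <- function(n_sites = c(allopatric_A = 9L, allopatric_B = 5L,
                                         allotopic_A = 7L, allotopic_B = 7L,
                                         syntopic = 8L),
                             samples_per_site = 5L,
                             n_bins_total = 150L,
                             pool_size = 60L,
                             pool_overlap = 0.5,
                             pool_conc = 1.0,
                             syntopic_shift = 0,
                             mean_items = 18,
                             reads_per_run_mean = 3000,
                             reads_dispersion = 3,
                             detection_bias = list(
                               A = c(Neuroptera = 0.5, Orthoptera = 0.6,
                                     Coleoptera = 0.7),
                               B = c(Trichoptera = 0.6, Blattodea = 0.7)),
                             blind_orders = "Opiliones",
                             blind_detection = 0.02,
                             dropout = 0.02,
                             n_contaminants = 3L,
                             blank_mean_reads = 20,
                             carry_prob = 0.3,
                             carry_mean = 50,
                             sweep_samples_per_site = 1L,
                             sweep_coverage = 0.5,
                             mean_items_sweep = 25,
                             sweep_reads_mean = 5000,
                             sweep_extra_bins = 12L,
                             sweep_extra_mass = 0.2,
                             n_noise_singletons = 3L,
                             morph_mean_individuals = 174,
                             batch_size = 16L,
                             category_mixture = NULL,
                             selection_shift = NULL,
                             seed = 1L) {
  cfg <- as.list(environment())
  strata <- c("allopatric_A", "allopatric_B", "allotopic_A", "allotopic_B",
              "syntopic")
  if (!all(strata %in% names(n_sites)))
    stop("n_sites must name all five strata", call. = FALSE)
  probs <- c(pool_overlap, syntopic_shift, dropout, carry_prob,
             sweep_coverage, sweep_extra_mass, blind_detection)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  n_shared <- round(pool_overlap * pool_size)
  n_blind <- if (length(blind_orders)) 4L else 0L
  n_needed <- 2L * pool_size - n_shared + n_contaminants +
    length(NOISE_ORDERS) * 3L + n_blind + sweep_extra_bins
  if (n_bins_total < n_needed)
    stop("infeasible config: n_bins_total = ", n_bins_total, " but ",
         n_needed, " BINs needed for pools, contaminants, noise, blind and ",
         "availability-only sets", call. = FALSE)
  if (!is.null(category_mixture)) {
    if (!setequal(names(category_mixture), FUNCTIONAL_CATEGORIES) ||
        abs(sum(category_mixture) - 1) > 1e-8)
      stop("category_mixture must be proportions over the three categories",
           call. = FALSE)
  }
  cfg$n_shared <- n_shared
  cfg$n_blind <- n_blind
  structure(cfg, class = "trophiq_config")
}

substream_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + k * 69621) %% 2147483629 + 1
}

det_prob <- function(cfg, primer, order) {
  p <- 1
  if (order %in% cfg$blind_orders) p <- cfg$blind_detection
  b <- cfg$detection_bias[[primer]]
  if (!is.null(b) && order %in% names(b)) p <- b[[order]]
  p
}

normalize <- function(x) x / sum(x)

shift_weights <- function(w, down_idx, shift) {
  w[down_idx] <- w[down_idx] * (1 - shift)
  normalize(w)
}

occurrence_truth <- function(w, mean_items, all_bins) {
  u <- setNames(numeric(length(all_bins)), all_bins)
  u[names(w)] <- 1 - exp(-mean_items * w)
  normalize(u)
}

sim_sample_runs <- function(cfg, w, mean_items, reads_mean, sample_id,
                            taxonomy_order, noise_bins = character(0)) {
  # item counts: Poisson intensity split over the pool by weight
  x <- rpois(length(w), mean_items * w)
  names(x) <- names(w)
  if (all(x == 0)) x[sample(length(w), 1L, prob = w)] <- 1L
  present <- names(x)[x > 0]
  rows <- list()
  for (primer in c("A", "B")) for (rep in c("1", "2")) {
    if (runif(1) < cfg$dropout) next
    det <- vapply(taxonomy_order[present], function(o)
      det_prob(cfg, primer, o), numeric(1))
    detected <- present[runif(length(present)) < det]
    n_reads <- rnbinom(1, mu = reads_mean, size = cfg$reads_dispersion)
    if (length(detected) && n_reads > 0) {
      r <- as.vector(rmultinom(1, n_reads, prob = x[detected]))
      keep <- r > 0
      if (any(keep))
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sample_id, primer_id = primer, replicate_id = rep,
          bin_id = detected[keep], reads = r[keep], stringsAsFactors = FALSE)
    }
    if (length(noise_bins) && cfg$n_noise_singletons > 0) {
      nb <- sample(noise_bins, min(cfg$n_noise_singletons, length(noise_bins)))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, primer_id = primer, replicate_id = rep,
        bin_id = nb, reads = 1L, stringsAsFactors = FALSE)
    }
    # contaminant carry-over, geometric-tailed so the 10x rule sees both
    # the removal and the retention branch
    for (cb in cfg$contaminant_bins) {
      if (runif(1) < cfg$carry_prob) {
        cr <- rgeom(1, 1 / (1 + cfg$carry_mean)) + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sample_id, primer_id = primer, replicate_id = rep,
          bin_id = cb, reads = cr, stringsAsFactors = FALSE)
      }
    }
  }
  rows
}

collapse_dup_runs <- function(df) {
  if (!nrow(df)) return(df)
  agg <- aggregate(reads ~ sample_id + primer_id + replicate_id + bin_id,
                   data = df, FUN = sum)
  agg
}

#' Generate a complete synthetic study with known ground truth
#'
#' Produces the five study tables (read counts, metadata, taxonomy,
#' functional rules, morphology counts) plus a `truth` list holding the
#' generator's ground truth: per-species, per-stratum true prey-use
#' vectors (normalized expected occurrence probabilities
#' `u_i` proportional to `1 - exp(-m w_i)`, the quantity wPOO estimates),
#' true Pianka overlap per stratum, contaminant BINs and detection
#' parameters. Fully deterministic given the config (hierarchical
#' per-sample seed substreams).
#'
#' @param cfg a [generator_config()].
#' @return list (class `"synthetic_study"`) with elements `reads`, `meta`,
#'   `taxonomy`, `functional`, `morph`, `truth`.
#' @export
generate_study <- function(cfg) {
  if (!inherits(cfg, "trophiq_config")) cfg <- do.call(generator_config, cfg)
  set.seed(substream_seed(cfg$seed, 0))

  ## ---- BIN universe and taxonomy -------------------------------------
  bins <- sprintf("BIN%04d", seq_len(cfg$n_bins_total))
  n_sh <- cfg$n_shared
  n_ex <- cfg$pool_size - n_sh
  idx <- 0L
  take <- function(n) {
    out <- bins[idx + seq_len(n)]
    idx <<- idx + n
    out
  }
  shared <- take(n_sh)
  excl_A <- take(n_ex)
  excl_B <- take(n_ex)
  contaminant_bins <- take(cfg$n_contaminants)
  noise_bins <- take(length(NOISE_ORDERS) * 3L)
  blind_bins <- take(cfg$n_blind)
  extra_bins <- take(cfg$sweep_extra_bins)
  pool_A <- c(shared, excl_A)
  pool_B <- c(shared, excl_B)
  poolable <- unique(c(pool_A, pool_B, extra_bins))

  order_of <- setNames(rep(NA_character_, length(bins)), bins)
  if (is.null(cfg$category_mixture)) {
    order_of[poolable] <- sample(names(DIET_ORDERS), length(poolable),
                                 replace = TRUE, prob = DIET_ORDERS)
  } else {
    # allocate categories in the requested proportions within each pool
    # subset, so every species pool carries the mixture (largest-remainder
    # rounding); orders drawn uniformly within category
    alloc <- function(g) {
      mx <- cfg$category_mixture
      n <- floor(mx * g)
      rem <- mx * g - n
      short <- g - sum(n)
      if (short > 0) {
        add <- order(rem, decreasing = TRUE)[seq_len(short)]
        n[add] <- n[add] + 1L
      }
      sample(rep(names(mx), times = n))
    }
    diet_cat <- ORDER_CATEGORY[names(DIET_ORDERS)]
    for (grp in list(shared, excl_A, excl_B, extra_bins)) {
      if (!length(grp)) next
      cats <- alloc(length(grp))
      order_of[grp] <- vapply(cats, function(cc) {
        cand <- names(diet_cat)[diet_cat == cc]
        cand[sample.int(length(cand), 1L)]
      }, character(1))
    }
  }
  order_of[contaminant_bins] <- "Hymenoptera"
  rest <- is.na(order_of)
  if (any(rest))  # unobserved reference taxa beyond the study's pools
    order_of[rest] <- sample(names(DIET_ORDERS), sum(rest), replace = TRUE,
                             prob = DIET_ORDERS)
  order_of[noise_bins] <- rep(NOISE_ORDERS, each = 3L)
  order_of[blind_bins] <- rep(cfg$blind_orders, length.out = cfg$n_blind)

  family_of <- paste0(substr(order_of, 1, 4), "idae")
  # a diurnal hoverfly family: stays Diptera but overrides the order rule
  dip <- if (is.null(cfg$category_mixture)) which(order_of == "Diptera")
         else integer(0)  # keep the planted mixture exact
  if (length(dip) >= 4L)
    family_of[sample(dip, max(2L, length(dip) %/% 8L))] <- "Syrphidae"
  taxonomy <- data.frame(bin_id = bins, order_name = unname(order_of),
                         family_name = family_of,
                         species_name = paste0("sp_", tolower(bins)),
                         stringsAsFactors = FALSE)

  orders_used <- unique(unname(order_of))
  functional <- data.frame(taxon_key = orders_used, rank = "order",
                           category = unname(ORDER_CATEGORY[orders_used]),
                           stringsAsFactors = FALSE)
  functional <- rbind(functional,
                      data.frame(taxon_key = "Syrphidae", rank = "family",
                                 category = "not_actively_volant",
                                 stringsAsFactors = FALSE))

  ## ---- utilization weights and truth ---------------------------------
  abundance <- if (is.null(cfg$category_mixture))
    setNames(rgamma(length(poolable), shape = cfg$pool_conc), poolable)
  else setNames(rep(1, length(poolable)), poolable)  # uniform use: the
  # planted category mixture is then exact at the pool level
  abundance[abundance < 1e-12] <- 1e-12
  w_base <- list(escalerai = normalize(abundance[pool_A]),
                 crypticus = normalize(abundance[pool_B]))
  half <- seq_len(n_sh %/% 2L)
  w_syn <- if (n_sh >= 2L) list(
    escalerai = shift_weights(w_base$escalerai, match(shared[-half], pool_A),
                              cfg$syntopic_shift),
    crypticus = shift_weights(w_base$crypticus, match(shared[half], pool_B),
                              cfg$syntopic_shift))
  else w_base
  weights <- list(allopatric = w_base, allotopic = w_base, syntopic = w_syn)

  use <- lapply(weights, function(wl)
    lapply(wl, occurrence_truth, mean_items = cfg$mean_items, all_bins = bins))
  n_allo <- (cfg$n_sites[["allotopic_A"]] + cfg$n_sites[["allotopic_B"]]) / 2
  n_syn <- cfg$n_sites[["syntopic"]]
  if (n_allo + n_syn == 0) n_allo <- 1  # no sympatric sites: base pools
  mix <- function(sp) normalize(
    use$allotopic[[sp]] * n_allo + use$syntopic[[sp]] * n_syn)
  use$sympatric <- list(escalerai = mix("escalerai"),
                        crypticus = mix("crypticus"))
  overlap <- vapply(use, function(uu)
    pianka(uu$escalerai, uu$crypticus), numeric(1))

  ## ---- sites and metadata --------------------------------------------
  site_rows <- list()
  layout <- list(
    allopatric_A = list(region = "south", lon = -3.2, lat = 37.5,
                        species = "escalerai", broad = "allopatric", fine = NA),
    allopatric_B = list(region = "atlantic", lon = -4.0, lat = 43.3,
                        species = "crypticus", broad = "allopatric", fine = NA),
    allotopic_A = list(region = "sympatric_zone", lon = -3.0, lat = 42.0,
                       species = "escalerai", broad = "sympatric",
                       fine = "allotopic"),
    allotopic_B = list(region = "sympatric_zone", lon = -2.0, lat = 42.0,
                       species = "crypticus", broad = "sympatric",
                       fine = "allotopic"),
    syntopic = list(region = "sympatric_zone", lon = -2.5, lat = 42.0,
                    species = c("escalerai", "crypticus"), broad = "sympatric",
                    fine = "syntopic"))
  for (st in names(layout)) {
    L <- layout[[st]]
    n <- cfg$n_sites[[st]]
    if (n < 1L) next
    for (i in seq_len(n)) {
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        site_id = sprintf("%s_%02d", toupper(substr(st, 1, 3)),
                          i + 100L * match(st, names(layout))),
        stratum_type = st, region_id = L$region,
        longitude = L$lon, latitude = L$lat + (i - 1) * 0.1,
        broad_class = L$broad, fine_class = L$fine,
        species = paste(L$species, collapse = "+"),
        stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, site_rows)

  meta_rows <- list()
  samp_plan <- list()
  k <- 0L
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    spp <- strsplit(s$species, "+", fixed = TRUE)[[1]]
    stratum <- if (s$broad_class == "allopatric") "allopatric"
               else if (s$fine_class == "syntopic") "syntopic" else "allotopic"
    for (sp in spp) for (j in seq_len(cfg$samples_per_site)) {
      k <- k + 1L
      id <- sprintf("D%04d", k)
      meta_rows[[length(meta_rows) + 1L]] <- data.frame(
        sample_id = id, sample_type = "dropping", bat_species = sp,
        site_id = s$site_id, region_id = s$region_id,
        broad_class = s$broad_class, fine_class = s$fine_class,
        longitude = s$longitude, latitude = s$latitude,
        stringsAsFactors = FALSE)
      samp_plan[[id]] <- list(kind = "dropping", species = sp,
                              stratum = stratum, site = s$site_id)
    }
    for (j in seq_len(cfg$sweep_samples_per_site)) {
      k <- k + 1L
      id <- sprintf("W%04d", k)
      meta_rows[[length(meta_rows) + 1L]] <- data.frame(
        sample_id = id, sample_type = "sweeping", bat_species = NA_character_,
        site_id = s$site_id, region_id = s$region_id,
        broad_class = s$broad_class, fine_class = s$fine_class,
        longitude = s$longitude, latitude = s$latitude,
        stringsAsFactors = FALSE)
      samp_plan[[id]] <- list(kind = "sweeping", species = spp,
                              stratum = stratum, site = s$site_id,
                              site_idx = i)
    }
  }
  meta <- do.call(rbind, meta_rows)
  meta$extraction_batch_id <- sprintf("batch%02d",
                                      (seq_len(nrow(meta)) - 1L) %/%
                                        cfg$batch_size + 1L)
  meta$sequencing_run_id <- "seqrun1"

  blanks <- data.frame(
    sample_id = c(paste0("BLK_EXT_", unique(meta$extraction_batch_id)),
                  "BLK_SEQ_1"),
    sample_type = c(rep("blank_extraction",
                        length(unique(meta$extraction_batch_id))),
                    "blank_sequencing"),
    bat_species = NA_character_, site_id = "lab", region_id = "lab",
    broad_class = NA_character_, fine_class = NA_character_,
    longitude = NA_real_, latitude = NA_real_,
    extraction_batch_id = c(unique(meta$extraction_batch_id), NA),
    sequencing_run_id = "seqrun1", stringsAsFactors = FALSE)
  meta <- rbind(meta, blanks)

  ## ---- availability compositions per site ----------------------------
  cfg$contaminant_bins <- contaminant_bins
  avail <- list()
  for (i in seq_len(nrow(sites))) {
    set.seed(substream_seed(cfg$seed, 500000 + i))
    s <- sites[i, ]
    spp <- strsplit(s$species, "+", fixed = TRUE)[[1]]
    stratum <- if (s$broad_class == "allopatric") "allopatric"
               else if (s$fine_class == "syntopic") "syntopic" else "allotopic"
    wl <- weights[[stratum]][spp]
    support <- unique(unlist(lapply(wl, names)))
    wd <- setNames(numeric(length(support)), support)
    for (w in wl) wd[names(w)] <- wd[names(w)] + w / length(wl)
    n_cov <- round(cfg$sweep_coverage * length(support))
    covered <- if (n_cov) sample(support, n_cov) else character(0)
    wa <- normalize(wd[covered])
    extras <- c(if (cfg$sweep_extra_bins) sample(extra_bins,
                  min(cfg$sweep_extra_bins, length(extra_bins))),
                blind_bins)
    if (length(extras) && cfg$sweep_extra_mass > 0 && length(wa)) {
      we <- normalize(setNames(rgamma(length(extras), 1), extras))
      wa <- c(wa * (1 - cfg$sweep_extra_mass), we * cfg$sweep_extra_mass)
    } else if (!length(wa) && length(extras)) {
      wa <- normalize(setNames(rgamma(length(extras), 1), extras))
    }
    if (!is.null(cfg$selection_shift)) {
      hit <- order_of[names(wa)] == cfg$selection_shift$order
      wa[hit] <- wa[hit] * cfg$selection_shift$factor
      wa <- normalize(wa)
    }
    avail[[s$site_id]] <- wa
  }

  ## ---- reads ----------------------------------------------------------
  all_rows <- list()
  ids <- names(samp_plan)
  for (si in seq_along(ids)) {
    id <- ids[si]
    plan <- samp_plan[[id]]
    set.seed(substream_seed(cfg$seed, 1000 + si))
    if (plan$kind == "dropping") {
      w <- weights[[plan$stratum]][[plan$species]]
      rows <- sim_sample_runs(cfg, w, cfg$mean_items, cfg$reads_per_run_mean,
                              id, order_of)
    } else {
      wa <- avail[[plan$site]]
      rows <- sim_sample_runs(cfg, wa, cfg$mean_items_sweep,
                              cfg$sweep_reads_mean, id, order_of,
                              noise_bins = noise_bins)
    }
    all_rows <- c(all_rows, rows)
  }
  ## blanks: contaminant BINs only
  for (bi in seq_len(nrow(blanks))) {
    set.seed(substream_seed(cfg$seed, 900000 + bi))
    id <- blanks$sample_id[bi]
    for (primer in c("A", "B")) for (rep in c("1", "2")) {
      if (!length(contaminant_bins)) next
      r <- rpois(length(contaminant_bins), cfg$blank_mean_reads)
      keep <- r > 0
      if (any(keep))
        all_rows[[length(all_rows) + 1L]] <- data.frame(
          sample_id = id, primer_id = primer, replicate_id = rep,
          bin_id = contaminant_bins[keep], reads = r[keep],
          stringsAsFactors = FALSE)
    }
  }
  reads <- collapse_dup_runs(do.call(rbind, all_rows))
  reads <- reads[order(reads$sample_id, reads$primer_id, reads$replicate_id,
                       reads$bin_id), , drop = FALSE]
  rownames(reads) <- NULL

  ## ---- morphology for sweep samples ----------------------------------
  morph_rows <- list()
  for (si in seq_along(ids)) {
    plan <- samp_plan[[ids[si]]]
    if (plan$kind != "sweeping") next
    set.seed(substream_seed(cfg$seed, 700000 + si))
    wa <- avail[[plan$site]]
    w_ord <- tapply(wa, order_of[names(wa)], sum)
    n_ind <- max(1L, rpois(1, cfg$morph_mean_individuals))
    counts <- as.vector(rmultinom(1, n_ind, prob = w_ord))
    keep <- counts > 0
    if (any(keep))
      morph_rows[[length(morph_rows) + 1L]] <- data.frame(
        sweep_sample_id = ids[si], order_name = names(w_ord)[keep],
        individuals = counts[keep], stringsAsFactors = FALSE)
  }
  morph <- do.call(rbind, morph_rows)
  if (is.null(morph))
    morph <- data.frame(sweep_sample_id = character(0),
                        order_name = character(0), individuals = integer(0))
  rownames(morph) <- NULL

  truth <- list(weights = weights, use = use, overlap = overlap,
                contaminant_bins = contaminant_bins,
                noise_bins = noise_bins, blind_bins = blind_bins,
                availability = avail,
                pools = list(escalerai = pool_A, crypticus = pool_B),
                detection_bias = cfg$detection_bias,
                category_mixture = cfg$category_mixture,
                selection_shift = cfg$selection_shift,
                seed = cfg$seed)

  structure(list(reads = validate_read_counts(reads, meta),
                 meta = validate_metadata(meta),
                 taxonomy = validate_taxonomy(taxonomy),
                 functional = validate_functional(functional),
                 morph = validate_morph(morph),
                 truth = truth, config = cfg),
            class = "synthetic_study")
}

#' True Pianka overlap between the species in a stratum
#'
#' @param truth the `truth` element of a [generate_study()] result (or the
#'   study itself).
#' @param stratum one of `"allopatric"`, `"allotopic"`, `"syntopic"`,
#'   `"sympatric"`.
#' @return overlap in `[0, 1]`.
#' @export
true_overlap <- function(truth, stratum) {
  if (inherits(truth, "synthetic_study")) truth <- truth$truth
  if (!stratum %in% names(truth$overlap))
    stop("unknown stratum: ", stratum, call. = FALSE)
  unname(truth$overlap[[stratum]])
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic metabarcoding diet study\n")
  cat("  ", sum(x$meta$sample_type == "dropping"), "dropping,",
      sum(x$meta$sample_type == "sweeping"), "sweeping,",
      sum(grepl("^blank", x$meta$sample_type)), "blank samples;",
      length(unique(x$reads$bin_id)), "BINs observed\n")
  cat("  true overlap:",
      paste(sprintf("%s=%.3f", names(x$truth$overlap), x$truth$overlap),
            collapse = ", "), "\n")
  invisible(x)
}
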
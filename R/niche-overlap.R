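#' Pianka's niche overlap index
#'
#' `O_jk = sum(p_j * p_k) / sqrt(sum(p_j^2) * sum(p_k^2))`, a symmetric
#' overlap measure on utilization vectors indexed over the same resource
#' states; 0 for disjoint use, 1 for identical use. Scale-invariant, so
#' unnormalized utilizations are accepted.
#'
#' @param p_j,p_k non-negative numeric vectors of equal length.
#' @return overlap in `[0, 1]`.
#' @export
pianka <- function(p_j, p_k) {
  if (length(p_j) != length(p_k))
    stop("utilization vectors must share resource states", call. = FALSE)
  sj <- sum(p_j^2); sk <- sum(p_k^2)
  if (sj == 0 || sk == 0) stop("zero utilization vector", call. = FALSE)
  sum(p_j * p_k) / sqrt(sj * sk)
}

align_union <- function(v1, v2) {
  items <- union(names(v1), names(v2))
  m <- matrix(0, 2, length(items), dimnames = list(NULL, items))
  m[1, names(v1)] <- v1
  m[2, names(v2)] <- v2
  m
}

randomize_row <- function(x, algorithm) {
  switch(algorithm,
    RA1 = runif(length(x)),
    RA2 = ifelse(x > 0, runif(length(x)), 0),
    RA3 = x[sample.int(length(x))],
    RA4 = { y <- x; nz <- which(x > 0); y[nz] <- x[nz][sample.int(length(nz))]; y })
}

#' Randomization null-model test of Pianka overlap
#'
#' Compares the observed Pianka overlap of two utilization rows against a
#' null distribution built by randomizing each row independently. The
#' default algorithm RA3 reshuffles each row's utilization values among all
#' resource states — niche breadth is retained while resource identity is
#' scrambled; zero states are reusable. RA1 replaces all values by uniform
#' random numbers, RA2 does so only for non-zero states, RA4 reshuffles
#' only among non-zero states.
#'
#' Both tail probabilities are returned with the add-one small-sample
#' correction: `p_high = (1 + #{null >= obs}) / (n_iter + 1)` and
#' symmetrically for `p_low`; ties count in both tails.
#'
#' @param utilization 2-row matrix (species x resource states) or a list of
#'   two named vectors (aligned on the union of names).
#' @param algorithm one of `"RA1"`, `"RA2"`, `"RA3"`, `"RA4"`.
#' @param n_iter number of null randomizations (default 1000).
#' @param seed optional integer seed for reproducibility.
#' @return object of class `"overlap_result"`: `observed`, `null_values`,
#'   `p_high`, `p_low`, `algorithm`, `n_iter`, `seed`.
#' @export
overlap_null_test <- function(utilization, algorithm = c("RA3", "RA1", "RA2", "RA4"),
                              n_iter = 1000L, seed = NULL) {
  algorithm <- match.arg(algorithm)
  if (is.list(utilization) && !is.matrix(utilization))
    utilization <- align_union(utilization[[1]], utilization[[2]])
  if (nrow(utilization) != 2L)
    stop("utilization matrix must have exactly 2 rows", call. = FALSE)
  if (ncol(utilization) < 2L)
    stop("degenerate utilization matrix: need >= 2 resource states", call. = FALSE)
  if (n_iter < 100L) warning("n_iter < 100 gives a coarse null distribution")
  if (!is.null(seed)) set.seed(seed)
  r1 <- utilization[1, ]; r2 <- utilization[2, ]
  obs <- pianka(r1, r2)
  null_values <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    null_values[i] <- pianka(randomize_row(r1, algorithm),
                             randomize_row(r2, algorithm))
  }
  structure(list(
    observed = obs,
    null_values = null_values,
    p_high = (1 + sum(null_values >= obs)) / (n_iter + 1),
    p_low = (1 + sum(null_values <= obs)) / (n_iter + 1),
    algorithm = algorithm, n_iter = n_iter, seed = seed),
    class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("Pianka niche overlap null-model test (", x$algorithm, ")\n", sep = "")
  cat(sprintf("  observed O_jk = %.4f\n", x$observed))
  cat(sprintf("  null mean = %.4f (%d iterations)\n", mean(x$null_values), x$n_iter))
  cat(sprintf("  Pr(null >= obs) = %.4f, Pr(null <= obs) = %.4f\n",
              x$p_high, x$p_low))
  invisible(x)
}

presence_matrix <- function(comp) {
  samples <- unique(comp$sample_id)
  bins <- sort(unique(comp$bin_id))
  m <- matrix(0L, length(samples), length(bins), dimnames = list(samples, bins))
  m[cbind(match(comp$sample_id, samples), match(comp$bin_id, bins))] <- 1L
  m
}

#' Jaccard distance matrix on BIN presence
#'
#' `d(s, t) = 1 - |s intersect t| / |s union t]` over the samples' BIN sets.
#' Empty samples are excluded with a warning.
#'
#' @param comp merged sample composition (`sample_id`, `bin_id`).
#' @return a `dist` object over samples.
#' @export
jaccard_matrix <- function(comp) {
  m <- presence_matrix(comp)
  empty <- rownames(m)[rowSums(m) == 0]
  if (length(empty)) {
    warning("excluding empty sample(s): ", paste(empty, collapse = ", "))
    m <- m[rowSums(m) > 0, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("need >= 2 non-empty samples", call. = FALSE)
  vegan::vegdist(m, method = "jaccard", binary = TRUE)
}

#' Analysis of similarities (ANOSIM)
#'
#' Tests whether distances between groups exceed distances within groups:
#' all off-diagonal distances are ranked (average ranks on ties) and
#' `R = (mean rank between - mean rank within) / (M/2)` with
#' `M = n(n-1)/2`; the permutation p-value is
#' `(1 + #{perm R >= obs}) / (n_perm + 1)` under random relabelling.
#'
#' @param dist a `dist` object.
#' @param groups group labels, one per object in `dist` (>= 2 groups with
#'   >= 2 members each).
#' @param n_perm number of label permutations (default 999).
#' @param seed optional integer seed.
#' @return object of class `"anosim_result"`: `R`, `p`, `n_perm`, `seed`.
#' @export
anosim_test <- function(dist, groups, n_perm = 999L, seed = NULL) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("every group needs >= 2 members", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::anosim(dist, groups, permutations = n_perm)
  structure(list(R = unname(fit$statistic), p = fit$signif,
                 n_perm = n_perm, seed = seed, vegan_fit = fit),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4f (%d permutations)\n",
              x$R, x$p, x$n_perm))
  invisible(x)
}

#' Stratum label per dropping sample
#'
#' Broad scale: `allopatric` / `sympatric` (excluded sites dropped).
#' Fine scale (within regional sympatry): `allotopic` / `syntopic`.
#'
#' @param meta sample metadata.
#' @param scale `"broad"` or `"fine"`.
#' @return named character vector sample_id -> stratum (NA when out of scope).
#' @export
sample_strata <- function(meta, scale = c("broad", "fine")) {
  scale <- match.arg(scale)
  drop_meta <- meta[meta$sample_type == "dropping", , drop = FALSE]
  s <- if (scale == "broad") {
    ifelse(drop_meta$broad_class %in% c("allopatric", "sympatric"),
           drop_meta$broad_class, NA_character_)
  } else {
    ifelse(drop_meta$broad_class == "sympatric", drop_meta$fine_class,
           NA_character_)
  }
  setNames(s, drop_meta$sample_id)
}

species_wpoo_pair <- function(comp, meta) {
  sp <- meta$bat_species[match(comp$sample_id, meta$sample_id)]
  if (length(unique(sp[!is.na(sp)])) < 2L) return(NULL)
  diets <- compute_wpoo(comp, groups = setNames(sp, comp$sample_id))
  v <- split(setNames(diets$proportion, diets$item), diets$unit_id)
  align_union(v[[1]], v[[2]])
}

#' Stratified niche overlap between the two species
#'
#' Per stratum (allopatric/sympatric at the broad scale; allotopic/syntopic
#' at the fine scale), pools each species' samples into a wPOO utilization
#' vector on the union of BINs and runs the randomization null-model test.
#' At the broad scale the allopatric stratum pairs each species' own
#' allopatric region samples. Strata missing a species are skipped with a
#' warning.
#'
#' @param comp merged sample composition.
#' @param meta sample metadata.
#' @param scale `"broad"` or `"fine"`.
#' @param algorithm,n_iter,seed passed to [overlap_null_test()].
#' @return named list of `overlap_result` objects, one per stratum.
#' @export
stratified_overlap <- function(comp, meta, scale = c("broad", "fine"),
                               algorithm = "RA3", n_iter = 1000L, seed = NULL) {
  scale <- match.arg(scale)
  strata <- sample_strata(meta, scale)
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (st in sort(unique(strata[!is.na(strata)]))) {
    sub <- comp[comp$sample_id %in% names(strata)[!is.na(strata) & strata == st],
                , drop = FALSE]
    u <- species_wpoo_pair(sub, meta)
    if (is.null(u)) {
      warning("stratum '", st, "' lacks one of the species; skipped")
      next
    }
    out[[st]] <- overlap_null_test(u, algorithm = algorithm, n_iter = n_iter)
  }
  out
}

#' Pairwise between-site niche overlap
#'
#' Pools each species' diet per site (wPOO) and computes Pianka overlap for
#' every pair of sites holding the two different species within the same
#' contrast: at the broad scale, pairs of allopatric sites (one per
#' species' allopatric region) versus pairs of sympatric sites; at the fine
#' scale, pairs of allotopic sites versus pairs of syntopic sites. The same
#' site is never paired with itself.
#'
#' @param comp merged sample composition.
#' @param meta sample metadata.
#' @param scale `"broad"` or `"fine"`.
#' @return data.frame `site_j`, `site_k`, `contrast`, `o_jk` where `site_j`
#'   holds *M. escalerai* samples and `site_k` *M. crypticus* samples.
#' @export
pairwise_site_overlap <- function(comp, meta, scale = c("broad", "fine")) {
  scale <- match.arg(scale)
  strata <- sample_strata(meta, scale)
  dm <- meta[meta$sample_type == "dropping", , drop = FALSE]
  info <- data.frame(sample_id = dm$sample_id, species = dm$bat_species,
                     site_id = dm$site_id,
                     stratum = unname(strata[dm$sample_id]),
                     stringsAsFactors = FALSE)
  info <- info[!is.na(info$stratum) & !is.na(info$species), , drop = FALSE]
  comp <- comp[comp$sample_id %in% info$sample_id, , drop = FALSE]
  unit <- paste(info$site_id, info$species, info$stratum, sep = "\r")
  diets <- compute_wpoo(comp, groups = setNames(unit[match(comp$sample_id,
                                                           info$sample_id)],
                                                comp$sample_id))
  vecs <- split(setNames(diets$proportion, diets$item), diets$unit_id)
  parts <- strsplit(names(vecs), "\r", fixed = TRUE)
  tab <- data.frame(site_id = vapply(parts, `[`, "", 1L),
                    species = vapply(parts, `[`, "", 2L),
                    stratum = vapply(parts, `[`, "", 3L),
                    stringsAsFactors = FALSE)
  rows <- list()
  for (st in unique(tab$stratum)) {
    j_idx <- which(tab$stratum == st & tab$species == BAT_SPECIES[1])
    k_idx <- which(tab$stratum == st & tab$species == BAT_SPECIES[2])
    for (j in j_idx) for (k in k_idx) {
      if (tab$site_id[j] == tab$site_id[k]) next
      m <- align_union(vecs[[j]], vecs[[k]])
      rows[[length(rows) + 1L]] <- data.frame(
        site_j = tab$site_id[j], site_k = tab$site_id[k], contrast = st,
        o_jk = pianka(m[1, ], m[2, ]), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(site_j = character(0), site_k = character(0),
                      contrast = character(0), o_jk = numeric(0)))
  do.call(rbind, rows)
}
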
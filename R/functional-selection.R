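#' Classify BINs into volancy categories
#'
#' Applies the functional rule table to the BIN taxonomy with the most
#' specific matching rule winning (species over family over order
#' fallback). BINs matching no rule are labelled `"unclassified"` and the
#' count is reported; conflicting rules at the same rank raise at
#' validation.
#'
#' @param taxonomy BIN taxonomy.
#' @param functional validated functional rule table
#'   (`taxon_key`, `rank`, `category`).
#' @return named character vector bin_id -> category.
#' @export
classify_bins <- function(taxonomy, functional) {
  functional <- validate_functional(functional)
  rule <- function(rank) {
    r <- functional[functional$rank == rank, , drop = FALSE]
    setNames(r$category, r$taxon_key)
  }
  by_sp <- rule("species"); by_fam <- rule("family"); by_ord <- rule("order")
  cat <- by_sp[taxonomy$species_name]
  fam <- by_fam[taxonomy$family_name]
  cat[is.na(cat)] <- fam[is.na(cat)]
  ord <- by_ord[taxonomy$order_name]
  cat[is.na(cat)] <- ord[is.na(cat)]
  n_un <- sum(is.na(cat))
  if (n_un) message(n_un, " BIN(s) unclassified (no matching functional rule)")
  cat[is.na(cat)] <- "unclassified"
  setNames(unname(cat), taxonomy$bin_id)
}

#' Functional diet composition and per-sample volancy response
#'
#' Computes the wPOO composition over the three volancy categories per unit
#' and the per-sample fraction of prey items (BINs) that are not
#' nocturnally volant (`non_volant` + `not_actively_volant`, divided by the
#' sample's classified BINs) — the response variable for testing gleaning
#' extent between species. Unclassified BINs are excluded from both
#' numerator and denominator; samples with zero classified BINs are
#' excluded with a warning.
#'
#' @param comp merged sample composition.
#' @param classification named vector from [classify_bins()].
#' @param groups optional named vector sample_id -> unit for the category
#'   composition (default: one pooled unit).
#' @return list with `composition` (unit_id, item, proportion) and
#'   `per_sample` (sample_id, n_classified, pct_not_nocturnally_volant).
#' @export
functional_diet <- function(comp, classification, groups = NULL) {
  cat <- classification[comp$bin_id]
  keep <- !is.na(cat) & cat != "unclassified"
  if (!all(keep)) {
    lost <- unique(comp$sample_id[!keep])
    gone <- setdiff(lost, unique(comp$sample_id[keep]))
    if (length(gone))
      warning(length(gone), " sample(s) with zero classified BINs excluded")
  }
  sub <- comp[keep, , drop = FALSE]
  if (!nrow(sub)) stop("no classified BINs in any sample", call. = FALSE)
  composition <- compute_wpoo(sub, level = "functional",
                              classification = classification, groups = groups)
  cc <- classification[sub$bin_id]
  n_cl <- tapply(rep(1L, nrow(sub)), sub$sample_id, sum)
  n_nnv <- tapply(cc != "nocturnally_volant", sub$sample_id, sum)
  per_sample <- data.frame(sample_id = names(n_cl),
                           n_classified = as.integer(n_cl),
                           pct_not_nocturnally_volant = as.numeric(n_nnv / n_cl),
                           stringsAsFactors = FALSE)
  rownames(per_sample) <- NULL
  list(composition = composition, per_sample = per_sample)
}

#' Representativeness of availability sampling per site
#'
#' For each site, the fraction of the site's diet BINs (over all dropping
#' samples) that also appear in the site's sweep samples. Sites are
#' retained when the fraction is at least `min_frac` (boundary inclusive);
#' sites without sweep data are excluded with a warning.
#'
#' @param diet_comp merged dropping-sample composition.
#' @param sweep_comp merged sweep-sample composition.
#' @param meta sample metadata (maps samples to sites).
#' @param min_frac retention threshold, default 0.20.
#' @return data.frame `site_id`, `fraction`, `retained`.
#' @export
representativeness_filter <- function(diet_comp, sweep_comp, meta,
                                      min_frac = 0.20) {
  site_of <- setNames(meta$site_id, meta$sample_id)
  d_site <- site_of[diet_comp$sample_id]
  s_site <- site_of[sweep_comp$sample_id]
  diet_bins <- lapply(split(diet_comp$bin_id, d_site), unique)
  sweep_bins <- lapply(split(sweep_comp$bin_id, s_site), unique)
  no_sweep <- setdiff(names(diet_bins), names(sweep_bins))
  if (length(no_sweep))
    warning("site(s) without sweep data excluded: ",
            paste(no_sweep, collapse = ", "))
  sites <- intersect(names(diet_bins), names(sweep_bins))
  frac <- vapply(sites, function(s)
    length(intersect(diet_bins[[s]], sweep_bins[[s]])) / length(diet_bins[[s]]),
    numeric(1))
  data.frame(site_id = sites, fraction = unname(frac),
             retained = unname(frac) >= min_frac, stringsAsFactors = FALSE)
}

#' Prey selection index per site (diet minus availability)
#'
#' Subtracts the availability wPOO (pooled sweep samples of the site) from
#' the diet wPOO (pooled dropping samples of the site) per item; positive
#' values indicate preferential consumption relative to the sampled
#' availability. Per site the selection values sum to zero (difference of
#' two simplex vectors).
#'
#' @param diet_site diet composition rows of one site (item, proportion).
#' @param avail_site availability composition rows of the same site.
#' @param site_id site label for the output.
#' @return data.frame `site_id`, `item`, `diet_wpoo`, `availability_wpoo`,
#'   `selection`.
#' @export
selection_index <- function(diet_site, avail_site, site_id = "site") {
  d <- setNames(diet_site$proportion, diet_site$item)
  a <- setNames(avail_site$proportion, avail_site$item)
  m <- align_union(d, a)
  data.frame(site_id = site_id, item = colnames(m),
             diet_wpoo = m[1, ], availability_wpoo = m[2, ],
             selection = m[1, ] - m[2, ],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize selection across sites
#'
#' Per item: quartiles (type 7) of the per-site selection values, a
#' percentile bootstrap confidence interval of the cross-site mean
#' (resampling sites with replacement), and a flag — `over` when the first
#' quartile is above zero, `under` when the third quartile is below zero,
#' `neutral` otherwise. With fewer than 3 sites the CI is suppressed with a
#' warning.
#'
#' @param rows selection table from [selection_index()] over several sites.
#' @param n_boot bootstrap draws, default 10000.
#' @param seed optional integer seed.
#' @param conf CI level, default 0.95.
#' @return data.frame per item: `n_sites`, `q1`, `median`, `q3`, `mean`,
#'   `ci_lo`, `ci_hi`, `flag`; class `"selection_summary"`.
#' @export
selection_summary <- function(rows, n_boot = 10000L, seed = NULL, conf = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  items <- sort(unique(rows$item))
  alpha <- (1 - conf) / 2
  out <- do.call(rbind, lapply(items, function(it) {
    v <- rows$selection[rows$item == it]
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    if (length(v) >= 3L) {
      bm <- vapply(seq_len(n_boot), function(i)
        mean(v[sample.int(length(v), replace = TRUE)]), numeric(1))
      ci <- quantile(bm, c(alpha, 1 - alpha), names = FALSE)
    } else ci <- c(NA_real_, NA_real_)
    data.frame(item = it, n_sites = length(v), q1 = q[1], median = q[2],
               q3 = q[3], mean = mean(v), ci_lo = ci[1], ci_hi = ci[2],
               flag = if (q[1] > 0) "over" else if (q[3] < 0) "under" else "neutral",
               stringsAsFactors = FALSE)
  }))
  if (any(table(rows$item) < 3L))
    warning("fewer than 3 sites for some item(s); CI suppressed")
  class(out) <- c("selection_summary", class(out))
  out
}

#' @export
print.selection_summary <- function(x, ...) {
  cat("Prey selection across", max(x$n_sites), "sites (diet - availability wPOO)\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Full prey-selection pipeline
#'
#' Applies the representativeness gate, pools diet and availability per
#' retained site at the requested level, computes per-site selection and
#' the cross-site summary.
#'
#' @param diet_comp merged dropping-sample composition.
#' @param sweep_comp merged sweep-sample composition.
#' @param meta sample metadata.
#' @param taxonomy BIN taxonomy (order level) .
#' @param classification functional classification (functional level).
#' @param level `"order"` (default) or `"functional"`.
#' @param min_frac representativeness threshold.
#' @param force compute even for sites failing the gate.
#' @param n_boot,seed passed to [selection_summary()].
#' @return list with `representativeness`, `selection` (per-site rows) and
#'   `summary`.
#' @export
prey_selection <- function(diet_comp, sweep_comp, meta, taxonomy = NULL,
                           classification = NULL, level = c("order", "functional"),
                           min_frac = 0.20, force = FALSE,
                           n_boot = 10000L, seed = NULL) {
  level <- match.arg(level)
  rep_tab <- representativeness_filter(diet_comp, sweep_comp, meta, min_frac)
  sites <- if (force) rep_tab$site_id else rep_tab$site_id[rep_tab$retained]
  if (!length(sites)) stop("no site passes the representativeness gate",
                           call. = FALSE)
  site_of <- setNames(meta$site_id, meta$sample_id)
  rows <- do.call(rbind, lapply(sites, function(s) {
    d <- diet_comp[site_of[diet_comp$sample_id] == s, , drop = FALSE]
    a <- sweep_comp[site_of[sweep_comp$sample_id] == s, , drop = FALSE]
    selection_index(
      compute_wpoo(d, level = level, taxonomy = taxonomy,
                   classification = classification),
      compute_wpoo(a, level = level, taxonomy = taxonomy,
                   classification = classification),
      site_id = s)
  }))
  # selection is defined for every item at every retained site: items absent
  # from both diet and availability score 0 there, and those zeros belong in
  # the cross-site quartiles
  grid <- expand.grid(site_id = unique(rows$site_id),
                      item = unique(rows$item),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  miss <- !paste(grid$site_id, grid$item) %in% paste(rows$site_id, rows$item)
  if (any(miss)) {
    zero <- data.frame(site_id = grid$site_id[miss], item = grid$item[miss],
                       diet_wpoo = 0, availability_wpoo = 0, selection = 0,
                       stringsAsFactors = FALSE)
    rows <- rbind(rows, zero)
  }
  rows <- rows[order(rows$site_id, rows$item), , drop = FALSE]
  list(representativeness = rep_tab, selection = rows,
       summary = selection_summary(rows, n_boot = n_boot, seed = seed))
}
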
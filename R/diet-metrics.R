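map_items <- function(bin_id, level, taxonomy = NULL, classification = NULL) {
  switch(level,
    bin = bin_id,
    order = {
      if (is.null(taxonomy)) stop("taxonomy required at order level", call. = FALSE)
      ord <- taxonomy$order_name[match(bin_id, taxonomy$bin_id)]
      if (anyNA(ord)) {
        warning(sum(is.na(ord)), " BIN(s) without order assignment counted as 'unassigned'")
        ord[is.na(ord)] <- "unassigned"
      }
      ord
    },
    functional = {
      if (is.null(classification))
        stop("classification required at functional level", call. = FALSE)
      classification[bin_id]
    },
    stop("unknown level: ", level, call. = FALSE))
}

diet_df <- function(v, unit_id, metric, level) {
  out <- data.frame(unit_id = unit_id, item = names(v),
                    proportion = as.numeric(v), stringsAsFactors = FALSE)
  attr(out, "metric") <- metric
  attr(out, "level") <- level
  out
}

metric_one_group <- function(comp, metric, level, taxonomy, classification) {
  item <- map_items(comp$bin_id, level, taxonomy, classification)
  keep <- !is.na(item) & item != "unclassified"
  comp <- comp[keep, , drop = FALSE]
  item <- item[keep]
  if (!nrow(comp)) stop("no classified items in any sample", call. = FALSE)
  samples <- unique(comp$sample_id)
  S <- length(samples)
  if (metric == "POO") {
    occ <- unique(data.frame(sample_id = comp$sample_id, item = item,
                             stringsAsFactors = FALSE))
    v <- table(occ$item)
    return(v / sum(v))
  }
  # per-sample shares then average (wPOO: item-count shares; RRA: read shares)
  weight <- if (metric == "wPOO") rep(1, nrow(comp)) else comp$reads
  denom <- ave(weight, comp$sample_id, FUN = sum)
  if (metric == "RRA" && any(denom == 0))
    warning("sample(s) with zero reads excluded from RRA")
  share <- weight / denom
  contrib <- tapply(share, item, sum)
  contrib / S
}

compute_metric <- function(comp, metric, level, taxonomy = NULL,
                           classification = NULL, groups = NULL) {
  if (!nrow(comp)) stop("empty composition", call. = FALSE)
  if (is.null(groups)) {
    v <- metric_one_group(comp, metric, level, taxonomy, classification)
    return(diet_df(v, "all", metric, level))
  }
  g <- groups[comp$sample_id]
  if (anyNA(g)) {
    warning(sum(is.na(g)), " record(s) of samples without a group excluded")
    comp <- comp[!is.na(g), , drop = FALSE]
    g <- g[!is.na(g)]
  }
  parts <- lapply(split(comp, g), metric_one_group, metric = metric,
                  level = level, taxonomy = taxonomy,
                  classification = classification)
  out <- do.call(rbind, Map(function(v, u) diet_df(v, u, metric, level),
                            parts, names(parts)))
  rownames(out) <- NULL
  attr(out, "metric") <- metric
  attr(out, "level") <- level
  out
}

#' Weighted percent of occurrence (wPOO)
#'
#' wPOO weighs each prey item's occurrence by its relative share of items
#' within the sample: an item found among `n` items in a sample contributes
#' `1/n` of what it would if it were the sample's only item. Per item `i`,
#' `wPOO_i = (1/S) * sum_s count_i(s) / n(s)` over the `S` samples; the
#' result sums to 1 over items.
#'
#' Item shares are always taken at the BIN level first and then collapsed
#' (summed) to coarser levels, so order- and functional-level wPOO reflect
#' the number of distinct prey items consumed.
#'
#' @param comp merged sample composition (`sample_id`, `bin_id`, `reads`).
#' @param level `"bin"`, `"order"` or `"functional"`.
#' @param taxonomy BIN taxonomy, required at order level.
#' @param classification named vector bin_id -> functional category
#'   (see [classify_bins()]), required at functional level; `unclassified`
#'   BINs are excluded.
#' @param groups optional named vector sample_id -> unit (species, site,
#'   ...); one composition per unit is returned.
#' @return data.frame `unit_id`, `item`, `proportion` (sums to 1 per unit).
#' @export
compute_wpoo <- function(comp, level = "bin", taxonomy = NULL,
                         classification = NULL, groups = NULL) {
  compute_metric(comp, "wPOO", level, taxonomy, classification, groups)
}

#' Percent of occurrence (POO)
#'
#' `POO_i` = number of samples containing item `i` divided by the total
#' number of item occurrences over all samples; presence-only, invariant
#' to read counts.
#'
#' @inheritParams compute_wpoo
#' @return data.frame `unit_id`, `item`, `proportion`.
#' @export
compute_poo <- function(comp, level = "bin", taxonomy = NULL,
                        classification = NULL, groups = NULL) {
  compute_metric(comp, "POO", level, taxonomy, classification, groups)
}

#' Relative read abundance (RRA)
#'
#' `RRA_i = (1/S) * sum_s reads_i(s) / reads_total(s)`: the mean across
#' samples of each item's within-sample read share.
#'
#' @inheritParams compute_wpoo
#' @return data.frame `unit_id`, `item`, `proportion`.
#' @export
compute_rra <- function(comp, level = "bin", taxonomy = NULL,
                        classification = NULL, groups = NULL) {
  comp <- comp[comp$reads > 0, , drop = FALSE]
  compute_metric(comp, "RRA", level, taxonomy, classification, groups)
}

#' Levins' niche breadth (standardized)
#'
#' `B = 1 / sum(p_i^2)` (reciprocal Simpson) and the standardized
#' `B_A = (B - 1) / (n - 1)`, ranging from 0 (single resource) to 1
#' (uniform use of all `n` resource states).
#'
#' @param p proportion vector (sums to 1).
#' @param n number of resource states; defaults to the number of items with
#'   non-zero proportion (the distinct prey items observed in the diet).
#' @return list with `B`, `B_A`, `n_items`.
#' @export
levins_breadth <- function(p, n = sum(p > 0)) {
  if (abs(sum(p) - 1) > 1e-6) stop("p must sum to 1", call. = FALSE)
  if (n < sum(p > 0)) stop("n smaller than the observed support", call. = FALSE)
  B <- 1 / sum(p^2)
  if (n <= 1L) {
    warning("n = 1: B_A defined as 0")
    return(list(B = B, B_A = 0, n_items = n))
  }
  list(B = B, B_A = (B - 1) / (n - 1), n_items = n)
}

#' Number of BINs per sample for a given order
#'
#' Response variable for downstream per-order models comparing prey-item
#' richness between species.
#'
#' @param comp merged sample composition.
#' @param taxonomy BIN taxonomy.
#' @param order_name arthropod order.
#' @return named integer vector, one count per sample.
#' @export
bins_per_sample_by_order <- function(comp, taxonomy, order_name) {
  ord <- map_items(comp$bin_id, "order", taxonomy)
  counts <- tapply(ord == order_name, comp$sample_id, sum)
  setNames(as.integer(counts), names(counts))
}

#' Per-sample BIN counts for every order (tidy table)
#'
#' @inheritParams bins_per_sample_by_order
#' @return data.frame `sample_id`, `order_name`, `n_bins`.
#' @export
bins_per_sample_table <- function(comp, taxonomy) {
  ord <- map_items(comp$bin_id, "order", taxonomy)
  agg <- aggregate(list(n_bins = rep(1L, nrow(comp))),
                   by = list(sample_id = comp$sample_id, order_name = ord),
                   FUN = sum)
  agg[order(agg$sample_id, agg$order_name), , drop = FALSE]
}

#' Orders constituting a major share of at least one unit's diet
#'
#' @param diet order-level diet composition with one or more units
#'   (typically the two bat species).
#' @param cutoff minimum proportion (boundary inclusive), default 0.10.
#' @return character vector of order names.
#' @export
major_orders <- function(diet, cutoff = 0.10) {
  sel <- diet$proportion >= cutoff
  sort(unique(diet$item[sel]))
}
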
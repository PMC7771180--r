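audit_record <- function(rule, reads, blank_reads = NA_real_) {
  if (!nrow(reads)) return(empty_audit())
  data.frame(rule = rule,
             sample_id = reads$sample_id,
             primer_id = reads$primer_id,
             replicate_id = reads$replicate_id,
             bin_id = reads$bin_id,
             reads_removed = reads$reads,
             blank_reads = blank_reads,
             stringsAsFactors = FALSE)
}

empty_audit <- function() {
  data.frame(rule = character(0), sample_id = character(0),
             primer_id = character(0), replicate_id = character(0),
             bin_id = character(0), reads_removed = numeric(0),
             blank_reads = numeric(0), stringsAsFactors = FALSE)
}

#' Remove low-read BIN records (singleton filtering)
#'
#' Drops every (sample, run, BIN) record whose read count is below
#' `min_reads`. With the default `min_reads = 2` this removes exactly the
#' singletons — BINs supported by a single read in a run — which are likely
#' PCR or sequencing errors.
#'
#' @param reads read-count table.
#' @param min_reads minimum reads for a BIN record to be retained
#'   (a record with exactly `min_reads` reads is kept).
#' @return list with the filtered `reads` and an `audit` data.frame logging
#'   each removed record under rule `"singleton"`.
#' @export
remove_low_read_bins <- function(reads, min_reads = 2L) {
  if (min_reads < 1L) stop("min_reads must be >= 1", call. = FALSE)
  drop <- reads$reads < min_reads
  list(reads = reads[!drop, , drop = FALSE],
       audit = audit_record("singleton", reads[drop, , drop = FALSE]))
}

order_presence_sets <- function(reads, taxonomy) {
  ord <- taxonomy$order_name[match(reads$bin_id, taxonomy$bin_id)]
  split(ord, reads$sample_id)
}

#' Calibrate the minimum-read threshold against morphology
#'
#' Scores candidate per-record read thresholds on sweep-net samples that
#' were identified both molecularly (BINs) and morphologically (order-level
#' counts): for each threshold the sweep read table is filtered, BINs are
#' collapsed to arthropod orders (presence/absence), and the mean per-sample
#' Jaccard similarity between the molecular and morphological order sets is
#' computed. The threshold maximizing mean similarity is chosen; ties break
#' toward the smaller threshold (retains more data).
#'
#' @param sweep_reads read-count table restricted to (or containing) the
#'   sweep samples listed in `morph`.
#' @param taxonomy BIN taxonomy.
#' @param morph morphological order counts per sweep sample.
#' @param thresholds integer candidates, default 1:5.
#' @param method similarity on order presence: `"jaccard"` (default) or
#'   `"braycurtis"` on within-sample order proportions of BIN counts.
#' @return list with `chosen` (integer) and `scores` (named numeric, one
#'   mean similarity per threshold).
#' @export
calibrate_min_read_threshold <- function(sweep_reads, taxonomy, morph,
                                         thresholds = 1:5,
                                         method = c("jaccard", "braycurtis")) {
  method <- match.arg(method)
  morph <- morph[morph$individuals > 0, , drop = FALSE]
  morph_sets <- lapply(split(morph$order_name, morph$sweep_sample_id), unique)
  common <- intersect(names(morph_sets), unique(sweep_reads$sample_id))
  if (!length(common))
    stop("no samples shared between molecular and morphological tables",
         call. = FALSE)
  scores <- vapply(thresholds, function(t) {
    kept <- remove_low_read_bins(sweep_reads, t)$reads
    kept <- kept[kept$sample_id %in% common, , drop = FALSE]
    ord <- taxonomy$order_name[match(kept$bin_id, taxonomy$bin_id)]
    mol_sets <- lapply(split(ord, factor(kept$sample_id, levels = common)), unique)
    sims <- vapply(common, function(s) {
      a <- mol_sets[[s]] %||% character(0)
      b <- morph_sets[[s]]
      if (method == "jaccard") {
        u <- union(a, b)
        if (!length(u)) return(1)
        length(intersect(a, b)) / length(u)
      } else {
        tab <- kept[kept$sample_id == s, , drop = FALSE]
        oa <- taxonomy$order_name[match(tab$bin_id, taxonomy$bin_id)]
        pa <- tapply(rep(1, length(oa)), oa, sum)
        pb <- tapply(morph$individuals[morph$sweep_sample_id == s],
                     morph$order_name[morph$sweep_sample_id == s], sum)
        items <- union(names(pa), names(pb))
        va <- setNames(numeric(length(items)), items); va[names(pa)] <- pa
        vb <- setNames(numeric(length(items)), items); vb[names(pb)] <- pb
        if (sum(va) > 0) va <- va / sum(va)
        if (sum(vb) > 0) vb <- vb / sum(vb)
        1 - sum(abs(va - vb)) / 2
      }
    }, numeric(1))
    mean(sims)
  }, numeric(1))
  names(scores) <- as.character(thresholds)
  list(chosen = thresholds[which.max(scores)], scores = scores)
}

blank_max_by_bin <- function(blank_reads) {
  if (!nrow(blank_reads)) return(numeric(0))
  tapply(blank_reads$reads, blank_reads$bin_id, max)
}

#' Remove blank-borne contamination (10x rule)
#'
#' BINs found in extraction or sequencing blanks are treated as potential
#' contaminants in the samples sharing that blank's scope: a sample/run
#' record of a blank BIN is removed when its read count is less than
#' `factor` times the blank's read count for that BIN (strictly; a record
#' with exactly `factor x blank` reads is retained). When several blanks
#' are in scope the maximum blank count per BIN is used (most conservative).
#' Extraction-blank and sequencing-blank rules are applied independently.
#'
#' Scoping: with `scope = "batch"`, extraction blanks act on samples of the
#' same `extraction_batch_id` (all runs), and sequencing blanks on samples
#' of the same `sequencing_run_id` compared within the same primer (primer
#' bias makes cross-primer comparisons meaningless). With `scope = "global"`
#' all non-blank samples are in scope of every blank.
#'
#' @param reads read-count table (samples and blanks).
#' @param meta sample metadata identifying blanks.
#' @param factor fold-difference threshold, default 10.
#' @param scope `"batch"` (default) or `"global"`.
#' @return list with filtered `reads` (blank records themselves retained,
#'   they are excluded downstream by sample type) and `audit`.
#' @export
filter_blank_contamination <- function(reads, meta, factor = 10,
                                       scope = c("batch", "global")) {
  scope <- match.arg(scope)
  if (factor <= 0) stop("factor must be > 0", call. = FALSE)
  type <- meta$sample_type[match(reads$sample_id, meta$sample_id)]
  audits <- list(empty_audit())
  any_blank <- FALSE

  apply_rule <- function(rule, blank_type, group_col, per_primer) {
    is_blank <- !is.na(type) & type == blank_type
    if (!any(is_blank)) return()
    any_blank <<- TRUE
    grp <- if (scope == "batch" && !is.null(meta[[group_col]]))
      meta[[group_col]][match(reads$sample_id, meta$sample_id)]
    else rep("all", nrow(reads))
    for (g in unique(grp[is_blank])) {
      in_g <- !is.na(grp) & grp == g
      br <- reads[in_g & is_blank, , drop = FALSE]
      primers <- if (per_primer) unique(br$primer_id) else "any"
      for (p in primers) {
        bp <- if (per_primer) br[br$primer_id == p, , drop = FALSE] else br
        rb <- blank_max_by_bin(bp)
        if (!length(rb)) next
        target <- in_g & !is.na(type) & type %in% c("dropping", "sweeping")
        if (per_primer) target <- target & reads$primer_id == p
        cand <- target & reads$bin_id %in% names(rb)
        if (!any(cand)) next
        thr <- factor * rb[reads$bin_id[cand]]
        rm_idx <- which(cand)[reads$reads[cand] < thr]
        if (length(rm_idx)) {
          audits[[length(audits) + 1L]] <<- audit_record(
            rule, reads[rm_idx, , drop = FALSE],
            blank_reads = unname(rb[reads$bin_id[rm_idx]]))
          drop_flags[rm_idx] <<- TRUE
        }
      }
    }
  }

  drop_flags <- logical(nrow(reads))
  apply_rule("blank_extraction", "blank_extraction", "extraction_batch_id",
             per_primer = FALSE)
  apply_rule("blank_sequencing", "blank_sequencing", "sequencing_run_id",
             per_primer = TRUE)
  if (!any_blank) {
    warning("no blanks in scope; contamination filter is a no-op")
    return(list(reads = reads, audit = empty_audit()))
  }
  list(reads = reads[!drop_flags, , drop = FALSE],
       audit = do.call(rbind, audits))
}

drop_blank_samples <- function(reads, meta) {
  type <- meta$sample_type[match(reads$sample_id, meta$sample_id)]
  reads[is.na(type) | !grepl("^blank", type), , drop = FALSE]
}

#' Combine PCR replicates additively (per sample and primer)
#'
#' The additive criterion unions the BIN sets of the two PCR replicates of
#' each sample x primer and sums their reads.
#'
#' @param reads read-count table.
#' @return data.frame `sample_id`, `primer_id`, `bin_id`, `reads`.
#' @export
combine_replicates_additive <- function(reads) {
  if (!nrow(reads))
    return(data.frame(sample_id = character(0), primer_id = character(0),
                      bin_id = character(0), reads = numeric(0)))
  agg <- aggregate(reads ~ sample_id + primer_id + bin_id, data = reads, FUN = sum)
  agg[order(agg$sample_id, agg$primer_id, agg$bin_id), , drop = FALSE]
}

#' Combine PCR replicates conservatively
#'
#' Under the conservative criterion a BIN is retained for a sample x primer
#' only when it appears in both PCR replicates, and a sample is considered
#' at all only when each of its four runs (2 primers x 2 replicates) holds
#' strictly more than `min_run_reads` total reads — a failed run would
#' otherwise annul a whole primer's composition. Samples with missing runs
#' are dropped and reported.
#'
#' @param reads read-count table.
#' @param min_run_reads run-total threshold; a run with exactly this many
#'   reads (or fewer) causes the sample to be dropped.
#' @return list with `composition` (sample_id, primer_id, bin_id, reads —
#'   reads summed over the two replicates) and `dropped_samples`.
#' @export
combine_replicates_conservative <- function(reads, min_run_reads = 100L) {
  samples <- unique(reads$sample_id)
  primers <- sort(unique(reads$primer_id))
  reps <- sort(unique(reads$replicate_id))
  if (length(primers) != 2L || length(reps) != 2L)
    stop("conservative criterion expects exactly 2 primers x 2 replicates; got ",
         length(primers), " primer(s) x ", length(reps), " replicate(s)",
         call. = FALSE)
  run_tot <- aggregate(reads ~ sample_id + primer_id + replicate_id,
                       data = reads, FUN = sum)
  dropped <- character(0)
  keep <- character(0)
  for (s in samples) {
    rt <- run_tot[run_tot$sample_id == s, , drop = FALSE]
    ok <- nrow(rt) == 4L && all(rt$reads > min_run_reads)
    if (ok) keep <- c(keep, s) else dropped <- c(dropped, s)
  }
  sub <- reads[reads$sample_id %in% keep, , drop = FALSE]
  if (nrow(sub)) {
    key <- paste(sub$sample_id, sub$primer_id, sub$bin_id, sep = "\r")
    n_rep <- ave(rep(1L, nrow(sub)), key, FUN = sum)
    sub <- sub[n_rep == 2L, , drop = FALSE]
  }
  comp <- combine_replicates_additive(sub)
  list(composition = comp, dropped_samples = dropped)
}

#' Union prey composition across primers
#'
#' Collapses the per-primer compositions of each sample to a single prey
#' composition: BIN presence is the union over primers, duplicate BINs are
#' merged and their reads summed (reads matter only for RRA).
#'
#' @param per_primer data.frame `sample_id`, `primer_id`, `bin_id`, `reads`.
#' @return data.frame `sample_id`, `bin_id`, `reads` (class kept plain).
#' @export
merge_primers <- function(per_primer) {
  if (!nrow(per_primer))
    return(data.frame(sample_id = character(0), bin_id = character(0),
                      reads = numeric(0)))
  agg <- aggregate(reads ~ sample_id + bin_id, data = per_primer, FUN = sum)
  agg[order(agg$sample_id, agg$bin_id), , drop = FALSE]
}

#' Per-order primer recovery summary
#'
#' For each arthropod order, counts the BINs recovered exclusively by each
#' primer and by both, over all samples.
#'
#' @param per_primer data.frame `sample_id`, `primer_id`, `bin_id` (reads
#'   optional); must contain exactly two primers.
#' @param taxonomy BIN taxonomy.
#' @return data.frame with per-order counts and proportions
#'   (`n_only_<primer1>`, `n_only_<primer2>`, `n_both`, matching `prop_*`).
#' @export
primer_recovery_summary <- function(per_primer, taxonomy) {
  primers <- sort(unique(per_primer$primer_id))
  if (length(primers) != 2L) stop("expected exactly two primers", call. = FALSE)
  b1 <- unique(per_primer$bin_id[per_primer$primer_id == primers[1]])
  b2 <- unique(per_primer$bin_id[per_primer$primer_id == primers[2]])
  all_bins <- union(b1, b2)
  ord <- taxonomy$order_name[match(all_bins, taxonomy$bin_id)]
  ord[is.na(ord)] <- "unassigned"
  cls <- ifelse(all_bins %in% b1 & all_bins %in% b2, "both",
                ifelse(all_bins %in% b1, "only1", "only2"))
  out <- do.call(rbind, lapply(unique(ord), function(o) {
    ci <- cls[ord == o]
    n <- length(ci)
    data.frame(order_name = o,
               n_only_1 = sum(ci == "only1"),
               n_only_2 = sum(ci == "only2"),
               n_both = sum(ci == "both"),
               prop_only_1 = sum(ci == "only1") / n,
               prop_only_2 = sum(ci == "only2") / n,
               prop_both = sum(ci == "both") / n,
               stringsAsFactors = FALSE)
  }))
  names(out) <- sub("_1$", paste0("_", primers[1]), names(out))
  names(out) <- sub("_2$", paste0("_", primers[2]), names(out))
  out[order(out$order_name), , drop = FALSE]
}

#' Run the full filtering stage
#'
#' Convenience wrapper applying, in order: low-read (singleton) removal,
#' blank-contamination removal, blank-sample exclusion, replicate
#' combination (additive or conservative), and primer union.
#'
#' @param reads read-count table.
#' @param meta sample metadata.
#' @param min_reads per-record read threshold (default 2 = remove singletons).
#' @param blank_factor fold threshold of the blank rule.
#' @param blank_scope `"batch"` or `"global"`.
#' @param replicate_mode `"additive"` (default) or `"conservative"`.
#' @param min_run_reads run-total threshold for the conservative mode.
#' @return list with `composition` (sample_id, bin_id, reads after primer
#'   union), `per_primer`, `audit`, `dropped_samples`.
#' @export
filter_study <- function(reads, meta, min_reads = 2L, blank_factor = 10,
                         blank_scope = c("batch", "global"),
                         replicate_mode = c("additive", "conservative"),
                         min_run_reads = 100L) {
  replicate_mode <- match.arg(replicate_mode)
  blank_scope <- match.arg(blank_scope)
  st1 <- remove_low_read_bins(reads, min_reads)
  st2 <- filter_blank_contamination(st1$reads, meta, blank_factor, blank_scope)
  kept <- drop_blank_samples(st2$reads, meta)
  dropped <- character(0)
  if (replicate_mode == "additive") {
    per_primer <- combine_replicates_additive(kept)
  } else {
    cr <- combine_replicates_conservative(kept, min_run_reads)
    per_primer <- cr$composition
    dropped <- cr$dropped_samples
  }
  list(composition = merge_primers(per_primer),
       per_primer = per_primer,
       audit = rbind(st1$audit, st2$audit),
       dropped_samples = dropped)
}
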
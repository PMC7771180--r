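#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate ave quantile rbinom rgeom rmultinom rnbinom
#'   rpois runif setNames rgamma sd
#' @importFrom utils read.delim write.table head
NULL

SAMPLE_TYPES <- c("dropping", "sweeping", "blank_extraction", "blank_sequencing")
BAT_SPECIES <- c("escalerai", "crypticus")
FUNCTIONAL_CATEGORIES <- c("non_volant", "not_actively_volant", "nocturnally_volant")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_rows <- function(msg, rows) {
  stop(msg, " (rows: ", paste(utils::head(rows, 10L), collapse = ", "),
       if (length(rows) > 10L) ", ..." else "", ")", call. = FALSE)
}

need_cols <- function(x, cols, what) {
  miss <- setdiff(cols, names(x))
  if (length(miss))
    stop(what, ": missing column(s) ", paste(miss, collapse = ", "), call. = FALSE)
}

#' Validate a long-format read-count table
#'
#' A read-count table holds one row per (sample, primer, PCR replicate, BIN)
#' with a non-negative integer read count. BINs (Barcode Index Numbers) are
#' the prey-item taxonomic units.
#'
#' @param reads data.frame with columns `sample_id`, `primer_id`,
#'   `replicate_id`, `bin_id`, `reads`.
#' @param meta optional sample metadata; if given, every `sample_id` must
#'   be present in it.
#' @return the validated data.frame (invisibly usable), with `reads` as integer.
#' @export
validate_read_counts <- function(reads, meta = NULL) {
  need_cols(reads, c("sample_id", "primer_id", "replicate_id", "bin_id", "reads"),
            "read-count table")
  reads$primer_id <- as.character(reads$primer_id)
  reads$replicate_id <- as.character(reads$replicate_id)
  reads$reads <- as.numeric(reads$reads)
  bad <- which(is.na(reads$reads) | reads$reads < 0 | reads$reads != round(reads$reads))
  if (length(bad)) stop_rows("read-count table: negative or non-integer reads", bad)
  key <- paste(reads$sample_id, reads$primer_id, reads$replicate_id, reads$bin_id,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) stop_rows("read-count table: duplicate (sample, run, bin) keys", dup)
  if (!is.null(meta)) {
    unk <- which(!reads$sample_id %in% meta$sample_id)
    if (length(unk)) stop_rows("read-count table: sample_id absent from metadata", unk)
  }
  reads$reads <- as.integer(round(reads$reads))
  reads
}

#' Validate sample metadata
#'
#' @param meta data.frame with columns `sample_id`, `sample_type`,
#'   `bat_species`, `site_id`, `region_id`, `broad_class`, `fine_class`,
#'   `extraction_batch_id`, `sequencing_run_id` and optional
#'   `longitude`/`latitude` in decimal degrees (WGS84).
#' @return validated data.frame.
#' @export
validate_metadata <- function(meta) {
  need_cols(meta, c("sample_id", "sample_type", "bat_species", "site_id",
                    "broad_class", "fine_class"), "metadata")
  dup <- which(duplicated(meta$sample_id))
  if (length(dup)) stop_rows("metadata: duplicate sample_id", dup)
  bad <- which(!meta$sample_type %in% SAMPLE_TYPES)
  if (length(bad)) stop_rows("metadata: unknown sample_type", bad)
  blank <- grepl("^blank", meta$sample_type)
  bad <- which(blank & !is.na(meta$bat_species))
  if (length(bad)) stop_rows("metadata: blanks must have bat_species = NA", bad)
  bad <- which(!is.na(meta$bat_species) & !meta$bat_species %in% BAT_SPECIES)
  if (length(bad)) stop_rows("metadata: unknown bat_species", bad)
  bad <- which(!is.na(meta$fine_class) & meta$broad_class != "sympatric")
  if (length(bad)) stop_rows("metadata: fine_class set outside broad_class = sympatric", bad)
  meta
}

#' Validate a BIN taxonomy table
#' @param tax data.frame with `bin_id`, `order_name` and optional
#'   `family_name`, `species_name`.
#' @return validated data.frame.
#' @export
validate_taxonomy <- function(tax) {
  need_cols(tax, c("bin_id", "order_name"), "taxonomy")
  dup <- which(duplicated(tax$bin_id))
  if (length(dup)) stop_rows("taxonomy: duplicate bin_id", dup)
  bad <- which(is.na(tax$order_name) | !nzchar(tax$order_name))
  if (length(bad)) stop_rows("taxonomy: empty order_name", bad)
  if (is.null(tax$family_name)) tax$family_name <- NA_character_
  if (is.null(tax$species_name)) tax$species_name <- NA_character_
  tax
}

#' Validate a functional (volancy) classification table
#'
#' Rows map a taxon (species, family, or order fallback) to one of the
#' three volancy categories used to infer gleaning versus aerial hawking:
#' `non_volant`, `not_actively_volant`, `nocturnally_volant`.
#'
#' @param fun data.frame with `taxon_key`, `rank` (one of
#'   `"species"`, `"family"`, `"order"`) and `category`.
#' @return validated data.frame.
#' @export
validate_functional <- function(fun) {
  need_cols(fun, c("taxon_key", "rank", "category"), "functional table")
  bad <- which(!fun$category %in% FUNCTIONAL_CATEGORIES)
  if (length(bad)) stop_rows("functional table: unknown category", bad)
  bad <- which(!fun$rank %in% c("species", "family", "order"))
  if (length(bad)) stop_rows("functional table: unknown rank", bad)
  key <- paste(fun$rank, fun$taxon_key, sep = "\r")
  conf <- unique(key[duplicated(key)])
  for (k in conf) {
    cats <- unique(fun$category[key == k])
    if (length(cats) > 1L)
      stop("functional table: conflicting rules for taxon ",
           sub(".*\r", "", k), call. = FALSE)
  }
  fun[!duplicated(key), , drop = FALSE]
}

#' Validate a morphological order-count table for sweep samples
#' @param morph data.frame with `sweep_sample_id`, `order_name`, `individuals`.
#' @return validated data.frame.
#' @export
validate_morph <- function(morph) {
  need_cols(morph, c("sweep_sample_id", "order_name", "individuals"), "morphology table")
  bad <- which(is.na(morph$individuals) | morph$individuals < 0)
  if (length(bad)) stop_rows("morphology table: negative individuals", bad)
  morph
}

read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  read.delim(path, sep = sep, stringsAsFactors = FALSE,
             na.strings = c("NA", ""), check.names = FALSE)
}

#' Read and cross-validate a study's tables
#'
#' Reads the five tables of a study (reads, metadata, taxonomy, functional,
#' morphology) from delimiter-separated text (tab default, comma
#' auto-detected) and cross-references them: every sample in the read table
#' must exist in the metadata and unknown BINs in the taxonomy raise.
#'
#' @param paths named list/vector with elements `reads`, `meta`, `taxonomy`,
#'   `functional`, `morph` (the last two optional).
#' @return a list of validated data.frames (class `"trophiq_study"`).
#' @export
read_study_tables <- function(paths) {
  reads <- validate_read_counts(read_table_auto(paths[["reads"]]))
  meta <- validate_metadata(read_table_auto(paths[["meta"]]))
  reads <- validate_read_counts(reads, meta)
  taxonomy <- validate_taxonomy(read_table_auto(paths[["taxonomy"]]))
  unk <- which(!reads$bin_id %in% taxonomy$bin_id)
  if (length(unk)) stop_rows("read-count table: bin_id absent from taxonomy", unk)
  functional <- if (!is.null(paths[["functional"]]))
    validate_functional(read_table_auto(paths[["functional"]])) else NULL
  morph <- if (!is.null(paths[["morph"]]))
    validate_morph(read_table_auto(paths[["morph"]])) else NULL
  structure(list(reads = reads, meta = meta, taxonomy = taxonomy,
                 functional = functional, morph = morph),
            class = "trophiq_study")
}

#' Write a study's tables as tab-separated text
#'
#' @param study list as returned by [read_study_tables()] or
#'   [generate_study()] (any `truth` element is skipped).
#' @param dir output directory, created if needed.
#' @return invisibly, the written file paths.
#' @export
write_study_tables <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- intersect(names(study), c("reads", "meta", "taxonomy", "functional", "morph"))
  out <- character(0)
  for (n in nm) {
    if (is.null(study[[n]])) next
    p <- file.path(dir, paste0(n, ".tsv"))
    write.table(study[[n]], p, sep = "\t", quote = FALSE, row.names = FALSE)
    out[n] <- p
  }
  invisible(out)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km between points in
#' decimal degrees (WGS84 longitudes/latitudes).
#'
#' @param lon1,lat1,lon2,lat2 numeric vectors of coordinates.
#' @return numeric vector of distances in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371.0088e3) / 1000
}

#' Classify sites as syntopic or allotopic from species records
#'
#' A site is syntopic when any record of the other bat species lies within
#' `radius_km` great-circle kilometres (boundary inclusive); otherwise
#' allotopic. The default 3 km reflects a conservative home-range distance
#' for the *Myotis nattereri* complex.
#'
#' @param records data.frame with one row per species record:
#'   `site_id`, `species`, `longitude`, `latitude`.
#' @param radius_km positive radius in km.
#' @return data.frame with `site_id` and `fine_class`
#'   (`"syntopic"`/`"allotopic"`), one row per site.
#' @export
classify_fine_scale <- function(records, radius_km = 3) {
  need_cols(records, c("site_id", "species", "longitude", "latitude"), "site records")
  if (radius_km <= 0) stop("radius_km must be > 0", call. = FALSE)
  miss <- unique(records$site_id[is.na(records$longitude) | is.na(records$latitude)])
  if (length(miss))
    stop("missing coordinates for site(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  sites <- unique(records$site_id)
  fine <- vapply(sites, function(s) {
    here <- records[records$site_id == s, , drop = FALSE]
    other <- records[!records$species %in% here$species, , drop = FALSE]
    if (length(unique(here$species)) > 1L) return("syntopic")
    if (!nrow(other)) return("allotopic")
    d <- outer(seq_len(nrow(here)), seq_len(nrow(other)), function(i, j)
      haversine_km(here$longitude[i], here$latitude[i],
                   other$longitude[j], other$latitude[j]))
    if (min(d) <= radius_km) "syntopic" else "allotopic"
  }, character(1))
  data.frame(site_id = sites, fine_class = unname(fine),
             stringsAsFactors = FALSE)
}

#' Exclude sites (e.g. a swarming site) from spatial analyses
#'
#' Flags the listed sites as `broad_class = "excluded"` and clears their
#' `fine_class`, so their samples drop out of both broad- and fine-scale
#' contrasts. Swarming sites attract bats from tens of kilometres away, so
#' their samples carry no information about local foraging sympatry.
#'
#' @param meta sample metadata.
#' @param site_ids site identifiers to exclude (must exist in `meta`).
#' @return updated metadata.
#' @export
exclude_swarming <- function(meta, site_ids) {
  if (!length(site_ids)) return(meta)
  unk <- setdiff(site_ids, meta$site_id)
  if (length(unk)) stop("unknown site_id: ", paste(unk, collapse = ", "), call. = FALSE)
  sel <- meta$site_id %in% site_ids
  meta$broad_class[sel] <- "excluded"
  meta$fine_class[sel] <- NA_character_
  meta
}
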
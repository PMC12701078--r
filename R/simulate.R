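#' Simulation configuration for paired pre/post qPCR CT data
#'
#' Bundles and validates the parameters of the synthetic-data generator,
#' which emulates the study design the analysis assumes: a small paired
#' cohort profiled on a 384-assay miRNA array with heavy non-detection near
#' the limit of detection, an exogenous spike-in per sample, and optional
#' planted post-intervention shifts.
#'
#' All quantities are in PCR cycles. A *positive* planted shift makes the
#' post CT later, i.e. models downregulation; through \eqn{-\Delta CT}
#' normalization a shift of +4 cycles maps to an expected log2FC of -4.
#'
#' @param n_patients number of paired patients (default 5).
#' @param n_assays number of target miRNA assays (default 384; the spike-in
#'   is added on top).
#' @param spike_in_mean,spike_in_sd spike-in CT distribution
#'   (defaults 22.0, 0.3 cycles); the spike-in is never censored.
#' @param baseline_ct_mean,baseline_ct_sd_between_mirna per-miRNA baseline
#'   CT distribution for the well-expressed regime (defaults 30.0, 4.0).
#' @param noise_sd_within_patient technical/biological noise added to every
#'   measurement (default 1.0).
#' @param patient_offset_sd sd of the per-patient random offset shared by
#'   the pre and post sample (default 1.5); this is the pairing structure
#'   the paired t-test exploits.
#' @param ceiling limit of detection in cycles (default 40.0); draws at or
#'   above it are censored ("undetermined").
#' @param planted_effects numeric vector of post-sample CT shifts, named by
#'   target-assay index (`"1"`..`n_assays`) or unnamed (applied to the first
#'   assays); positive = downregulation. Default none.
#' @param fraction_near_lod fraction of miRNAs whose baseline comes from a
#'   high-CT regime near the ceiling (default 0.4).
#' @param near_lod_ct_mean,near_lod_ct_sd high-CT regime parameters
#'   (defaults 38.0, 1.5).
#' @param planted_detectable keep planted assays out of the near-LOD regime
#'   (default `TRUE`), so that planted effects emulate hits that pass the
#'   detection filter.
#' @param spike_in_assay label of the spike-in assay
#'   (default `"cel-miR-39-3p"`).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 5, n_assays = 384,
                       spike_in_mean = 22.0, spike_in_sd = 0.3,
                       baseline_ct_mean = 30.0,
                       baseline_ct_sd_between_mirna = 4.0,
                       noise_sd_within_patient = 1.0,
                       patient_offset_sd = 1.5,
                       ceiling = 40.0,
                       planted_effects = numeric(0),
                       fraction_near_lod = 0.4,
                       near_lod_ct_mean = 38.0, near_lod_ct_sd = 1.5,
                       planted_detectable = TRUE,
                       spike_in_assay = "cel-miR-39-3p") {
  if (n_patients < 2) stop("n_patients must be >= 2")
  if (n_assays < 1) stop("n_assays must be >= 1")
  sds <- c(spike_in_sd, baseline_ct_sd_between_mirna,
           noise_sd_within_patient, patient_offset_sd, near_lod_ct_sd)
  if (any(sds < 0)) stop("standard deviations must be nonnegative")
  if (fraction_near_lod < 0 || fraction_near_lod > 1)
    stop("fraction_near_lod must be in [0, 1]")
  planted_effects <- unlist(planted_effects)
  if (length(planted_effects)) {
    if (is.null(names(planted_effects)))
      names(planted_effects) <- as.character(seq_along(planted_effects))
    idx <- as.integer(names(planted_effects))
    if (anyNA(idx) || any(idx < 1L) || any(idx > n_assays))
      stop("planted_effects must be named by assay indices in 1..n_assays")
  }
  structure(list(
    n_patients = n_patients, n_assays = n_assays,
    spike_in_mean = spike_in_mean, spike_in_sd = spike_in_sd,
    baseline_ct_mean = baseline_ct_mean,
    baseline_ct_sd_between_mirna = baseline_ct_sd_between_mirna,
    noise_sd_within_patient = noise_sd_within_patient,
    patient_offset_sd = patient_offset_sd,
    ceiling = ceiling, planted_effects = planted_effects,
    fraction_near_lod = fraction_near_lod,
    near_lod_ct_mean = near_lod_ct_mean, near_lod_ct_sd = near_lod_ct_sd,
    planted_detectable = planted_detectable,
    spike_in_assay = spike_in_assay), class = "sim_config")
}

#' Simulate a paired pre/post CT matrix
#'
#' Generates a [ct_matrix()] under the model
#' \deqn{CT_{ij}^{tp} = b_i + u_j + \epsilon_{ij}^{tp} + \delta_i
#'   \cdot [tp = post],}
#' where `b_i` is a per-miRNA baseline (drawn from the well-expressed regime
#' or, with probability `fraction_near_lod`, from a high-CT regime near the
#' ceiling), `u_j` a per-patient offset shared between the patient's pre and
#' post samples, `eps` i.i.d. measurement noise, and `delta_i` the planted
#' post shift. Any draw at or above the ceiling is censored to the ceiling
#' and flagged not-detected ("undetermined"); the spike-in is drawn per
#' sample and never censored.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; identical config + seed give byte-identical
#'   output.
#' @return list with `ct` (a `ct_matrix`) and `truth` (a `sim_truth`:
#'   `planted_down_ids`, `planted_up_ids`, and the full named `shifts`
#'   vector, zero for unplanted assays).
#' @export
simulate_ct <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    ids <- sprintf("hsa-miR-sim%04d", seq_len(cf$n_assays))
    shifts <- stats::setNames(numeric(cf$n_assays), ids)
    planted_idx <- integer(0)
    if (length(cf$planted_effects)) {
      planted_idx <- as.integer(names(cf$planted_effects))
      shifts[planted_idx] <- as.numeric(cf$planted_effects)
    }

    near_lod <- stats::runif(cf$n_assays) < cf$fraction_near_lod
    if (cf$planted_detectable) near_lod[planted_idx] <- FALSE
    b <- ifelse(near_lod,
                stats::rnorm(cf$n_assays, cf$near_lod_ct_mean,
                             cf$near_lod_ct_sd),
                stats::rnorm(cf$n_assays, cf$baseline_ct_mean,
                             cf$baseline_ct_sd_between_mirna))

    patients <- sprintf("P%02d", seq_len(cf$n_patients))
    u <- stats::rnorm(cf$n_patients, 0, cf$patient_offset_sd)
    sample_ids <- c(paste0(patients, "_pre"), paste0(patients, "_post"))
    meta <- data.frame(
      sample_id = sample_ids,
      patient_id = rep(patients, 2L),
      timepoint = rep(c("pre", "post"), each = cf$n_patients),
      stringsAsFactors = FALSE)

    n_s <- length(sample_ids)
    eps <- matrix(stats::rnorm(cf$n_assays * n_s, 0,
                               cf$noise_sd_within_patient),
                  cf$n_assays, n_s)
    post_cols <- meta$timepoint == "post"
    ct <- b + eps
    ct <- ct + matrix(rep(u, 2L), cf$n_assays, n_s, byrow = TRUE)
    ct[, post_cols] <- ct[, post_cols] + shifts
    dimnames(ct) <- list(ids, sample_ids)

    spike <- stats::rnorm(n_s, cf$spike_in_mean, cf$spike_in_sd)
    ct <- rbind(ct, matrix(spike, 1L, n_s,
                           dimnames = list(cf$spike_in_assay, sample_ids)))

    x <- ct_matrix(ct, meta, spike_in = cf$spike_in_assay,
                   ceiling = cf$ceiling)
    truth <- structure(
      list(planted_down_ids = ids[shifts > 0],
           planted_up_ids = ids[shifts < 0],
           shifts = shifts),
      class = "sim_truth")
    list(ct = x, truth = truth)
  })
}

#' Simulate a target map and gene-set collection with a known positive
#'
#' Builds the annotation side of the pipeline so that preranked GSEA has a
#' planted positive control: every simulated miRNA receives a random draw of
#' target genes from a common universe, and one designated gene set draws a
#' controllable fraction of its members from the union of targets of the
#' planted *down*-regulated miRNAs (whose targets receive high ranking
#' metrics after the sign flip). The remaining sets are random draws and
#' serve as the empirical null.
#'
#' @param truth a `sim_truth` from [simulate_ct()].
#' @param n_genes size of the gene universe (default 500).
#' @param targets_per_mirna targets drawn per miRNA (default 30).
#' @param n_sets number of random (null) gene sets in addition to the
#'   designated enriched one (default 20).
#' @param enriched_set_overlap fraction of the designated set drawn from
#'   planted-down targets (in (0, 1]; default 0.8).
#' @param set_size size of every gene set (default 50).
#' @param seed integer seed.
#' @return list with `targets` (a `target_map`), `collection`
#'   (a `gene_set_collection` of `n_sets + 1` sets), and `enriched_set`
#'   (the designated set's name, `"SIM_ENRICHED_TARGET_SET"`).
#' @export
simulate_targets_and_sets <- function(truth, n_genes = 500,
                                      targets_per_mirna = 30,
                                      n_sets = 20,
                                      enriched_set_overlap = 0.8,
                                      set_size = 50, seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  if (targets_per_mirna > n_genes)
    stop("targets_per_mirna exceeds n_genes")
  if (enriched_set_overlap <= 0 || enriched_set_overlap > 1)
    stop("enriched_set_overlap must be in (0, 1]")
  if (set_size > n_genes) stop("set_size exceeds n_genes")
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    genes <- sprintf("GENE%04d", seq_len(n_genes))
    mirnas <- names(truth$shifts)
    map <- lapply(stats::setNames(mirnas, mirnas), function(m)
      sort(sample(genes, targets_per_mirna)))
    names(map) <- normalize_mirna_id(names(map))$key
    targets <- structure(map, class = "target_map", n_malformed = 0L)

    down_keys <- normalize_mirna_id(truth$planted_down_ids)$key
    down_union <- sort(unique(unlist(targets[down_keys], use.names = FALSE)))
    n_from_down <- ceiling(enriched_set_overlap * set_size)
    if (n_from_down > length(down_union))
      stop("infeasible overlap: need ", n_from_down,
           " planted-down target genes but only ", length(down_union),
           " exist")
    outside <- setdiff(genes, down_union)
    if (set_size - n_from_down > length(outside))
      stop("infeasible set size: not enough genes outside the planted-down ",
           "target union")
    enriched <- sort(c(sample(down_union, n_from_down),
                       if (set_size > n_from_down)
                         sample(outside, set_size - n_from_down)))
    sets <- c(
      list(SIM_ENRICHED_TARGET_SET = enriched),
      lapply(stats::setNames(
        seq_len(n_sets),
        sprintf("SIM_RANDOM_SET_%02d", seq_len(n_sets))),
        function(i) sort(sample(genes, set_size))))
    collection <- structure(
      list(sets = sets,
           descriptions = stats::setNames(
             c("targets of planted down-regulated miRNAs",
               rep("random null set", n_sets)), names(sets))),
      class = "gene_set_collection")
    list(targets = targets, collection = collection,
         enriched_set = "SIM_ENRICHED_TARGET_SET")
  })
}

#' Write a target map as a two-column TSV
#' @param targets a `target_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_target_map <- function(targets, path) {
  stopifnot(inherits(targets, "target_map"))
  df <- data.frame(
    mirna = rep(names(targets), lengths(targets)),
    gene = unlist(targets, use.names = FALSE), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
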
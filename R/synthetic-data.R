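#' Simulation configuration for synthetic developmental time courses
#'
#' Describes a multi-species developmental expression dataset with planted
#' structure: temporally co-regulated archetypes (Gaussian activation
#' bumps over stage ordinals), a shared one-to-one orthologue core plus
#' species-specific genes, a planted subset of orthologues whose peak
#' stage is shifted in the second species (heterochrony), planted TF and
#' phylostratum label structure, and negative-binomial count noise with
#' log-normal library sizes.
#'
#' Defaults emulate the shape of a two-species annelid study: two species
#' with 10 ordered stages sampled in duplicate, 3,000 one-to-one
#' orthologues plus 300 species-specific genes each, 5 archetypes, 5% of
#' orthologues shifted by 3 stages from the early to the late phase, NB
#' dispersion 0.1. The peak amplitude over baseline is about 3 count-noise
#' SDs at the peak, the separation regime the recovery guarantees are
#' stated at.
#'
#' @param species list of per-species specs: `name`, `n_stages`,
#'   `n_replicates`, `n_early` (stages in the pre-larval phase).
#' @param n_orthologues number of one-to-one orthologous genes.
#' @param n_specific species-specific genes per species (no orthogroup).
#' @param n_archetypes number of temporal archetypes.
#' @param archetype_peaks optional numeric peak ordinals (species A
#'   scale); default evenly spaced over the stage range.
#' @param archetype_width Gaussian bump SD in stages.
#' @param baseline,amplitude expected counts off-peak and added at peak.
#' @param baseline_sdlog log-normal SD of the gene-specific baseline
#'   (shared across species for orthologues, emulating conserved
#'   per-gene expression levels).
#' @param dispersion negative-binomial dispersion (variance mu + disp
#'   mu^2); 0 gives deterministic expected counts.
#' @param libsize_sdlog log-normal SD of per-column library size factors.
#' @param heterochrony list: `fraction` of orthologues shifted, `shift`
#'   in stages, `direction` (`"early_to_late"` or `"late_to_early"`:
#'   shifted genes are drawn from the donor phase so the planted shift
#'   crosses the phase boundary).
#' @param labels list: `tf_fraction`, `n_tf_classes`,
#'   `enriched_archetype`, `enrichment_factor`, `strata`,
#'   `strata_probs`.
#' @param seed integer root seed.
#' @return a list of class `SimulationConfig`.
#' @export
simulation_config <- function(
    species = list(
      list(name = "species_a", n_stages = 10L, n_replicates = 2L,
           n_early = 5L),
      list(name = "species_b", n_stages = 10L, n_replicates = 2L,
           n_early = 5L)),
    n_orthologues = 3000L,
    n_specific = 300L,
    n_archetypes = 5L,
    archetype_peaks = NULL,
    archetype_width = 1.0,
    baseline = 5,
    baseline_sdlog = 1,
    amplitude = 150,
    dispersion = 0.1,
    libsize_sdlog = 0.1,
    heterochrony = list(fraction = 0.05, shift = 3L,
                        direction = "early_to_late"),
    labels = list(tf_fraction = 0.08, n_tf_classes = 36L,
                  enriched_archetype = 1L, enrichment_factor = 3,
                  strata = c("pre-metazoan", "metazoan", "bilaterian",
                             "lineage-specific"),
                  strata_probs = c(0.35, 0.3, 0.2, 0.15)),
    seed = 1L) {
  cfg <- structure(
    list(species = species, n_orthologues = as.integer(n_orthologues),
         n_specific = as.integer(n_specific),
         n_archetypes = as.integer(n_archetypes),
         archetype_peaks = archetype_peaks,
         archetype_width = archetype_width, baseline = baseline,
         baseline_sdlog = baseline_sdlog,
         amplitude = amplitude, dispersion = dispersion,
         libsize_sdlog = libsize_sdlog, heterochrony = heterochrony,
         labels = labels, seed = as.integer(seed)),
    class = "SimulationConfig")
  validate_config(cfg)
  cfg
}

#' @keywords internal
#' @noRd
validate_config <- function(cfg) {
  bad <- character(0)
  note <- function(cond, msg) if (!isTRUE(cond)) bad <<- c(bad, msg)
  note(length(cfg$species) >= 1, "at least one species required")
  for (sp in cfg$species) {
    note(sp$n_stages >= 2, paste0(sp$name, ": n_stages must be >= 2"))
    note(sp$n_replicates >= 1, paste0(sp$name, ": n_replicates >= 1"))
    note(sp$n_early >= 1 && sp$n_early < sp$n_stages,
         paste0(sp$name, ": n_early must split the stages"))
  }
  h <- cfg$heterochrony
  note(h$fraction >= 0 && h$fraction <= 1,
       "heterochrony fraction must lie in [0, 1]")
  note(h$shift < min(vapply(cfg$species, `[[`, integer(1), "n_stages")),
       "heterochrony shift must be smaller than the stage count")
  note(h$direction %in% c("early_to_late", "late_to_early"),
       "unknown heterochrony direction")
  note(cfg$n_orthologues >= 0 && cfg$n_specific >= 0,
       "gene counts must be >= 0")
  note(cfg$dispersion >= 0, "dispersion must be >= 0")
  note(cfg$labels$tf_fraction >= 0 && cfg$labels$tf_fraction <= 1,
       "tf_fraction must lie in [0, 1]")
  if (length(bad)) {
    stop("invalid simulation config:\n  - ",
         paste(bad, collapse = "\n  - "), call. = FALSE)
  }
  invisible(TRUE)
}

# Gaussian activation bump over stage ordinals.
#' @keywords internal
#' @noRd
bump_curve <- function(t, peak, width, baseline, amplitude) {
  baseline + amplitude * exp(-(t - peak)^2 / (2 * width^2))
}

# Default archetype layout: the early (pre-larval) phase gets a compact
# pair of archetypes, the late phase the remainder, mirroring the greater
# diversification of late development; peaks are kept off the phase
# boundary so cluster phase classes are stable under noise.
#' @keywords internal
#' @noRd
default_archetype_peaks <- function(cfg, ref) {
  k <- cfg$n_archetypes
  S <- ref$n_stages
  b <- ref$n_early
  n_early_arch <- max(1L, min(k - 1L, floor(k / 2)))
  c(seq(1, b - 1, length.out = n_early_arch),
    seq(b + 1, S, length.out = k - n_early_arch))
}

#' Simulate a multi-species developmental expression dataset
#'
#' Draws archetype mean curves, assigns genes to archetypes (orthologues
#' share their archetype across species except the planted heterochronic
#' subset, whose peak is moved by `shift` stages in the second species),
#' adds negative-binomial count noise and log-normal library sizes, and
#' derives a TPM layer by per-column scaling to one million.
#' Deterministic given the config seed.
#'
#' @param cfg a `SimulationConfig`.
#' @return a list of class `SyntheticBundle` with elements `expression`
#'   (per species: `counts` and `tpm` `ExpressionMatrix` objects with
#'   replicate maps), `map` (`OrthologyMap`), `annotation` (per species
#'   `GeneAnnotation`), `truth` (`TruthBundle`), `config`.
#' @export
simulate_dataset <- function(cfg) {
  assert_that(inherits(cfg, "SimulationConfig"), "not a SimulationConfig")
  validate_config(cfg)
  with_seed(cfg$seed, simulate_dataset_impl(cfg))
}

#' @keywords internal
#' @noRd
simulate_dataset_impl <- function(cfg) {
  ref <- cfg$species[[1]]
  S_ref <- ref$n_stages
  peaks <- cfg$archetype_peaks %||% default_archetype_peaks(cfg, ref)
  assert_that(length(peaks) == cfg$n_archetypes,
              "archetype_peaks length must equal n_archetypes")

  n_orth <- cfg$n_orthologues
  og_ids <- sprintf("OG%06d", seq_len(n_orth))
  orth_archetype <- sample.int(cfg$n_archetypes, n_orth, replace = TRUE)
  orth_peak_jitter <- stats::rnorm(n_orth, 0, 0.2)
  orth_amp <- cfg$amplitude * stats::rlnorm(n_orth, 0, 0.25)
  # per-gene baseline, conserved across species for orthologues
  orth_base <- cfg$baseline * stats::rlnorm(n_orth, 0, cfg$baseline_sdlog)

  # planted heterochrony: drawn from donor archetypes whose shifted peak
  # lands on the other side of the early/late boundary, so every planted
  # shift is a genuine phase change detectable by the quadrant rule
  h <- cfg$heterochrony
  donor_arch <- if (h$direction == "early_to_late") {
    which(peaks <= ref$n_early & peaks + h$shift > ref$n_early)
  } else {
    which(peaks > ref$n_early & peaks - h$shift <= ref$n_early)
  }
  donors <- which(orth_archetype %in% donor_arch)
  n_shift <- min(length(donors), round(h$fraction * n_orth))
  shifted_idx <- sort(sample(donors, n_shift))

  species_names <- vapply(cfg$species, `[[`, character(1), "name")
  expression <- list()
  annotation <- list()
  truth_arch <- list()
  gene_tables <- list()

  for (si in seq_along(cfg$species)) {
    sp <- cfg$species[[si]]
    S <- sp$n_stages
    # map archetype peaks onto this species' ordinal grid
    map_t <- function(t) 1 + (t - 1) * (S - 1) / (S_ref - 1)
    t_grid <- seq_len(S)

    n_spec <- cfg$n_specific
    gene_ids <- c(sprintf("%s_g%05d", sp$name, seq_len(n_orth)),
                  sprintf("%s_s%05d", sp$name, seq_len(n_spec)))
    spec_archetype <- if (n_spec > 0) {
      sample.int(cfg$n_archetypes, n_spec, replace = TRUE)
    } else integer(0)
    archetype <- c(orth_archetype, spec_archetype)
    peak <- map_t(peaks[archetype]) +
      c(orth_peak_jitter, stats::rnorm(n_spec, 0, 0.2))
    amp <- c(orth_amp, cfg$amplitude * stats::rlnorm(n_spec, 0, 0.25))
    base <- c(orth_base,
              cfg$baseline * stats::rlnorm(n_spec, 0, cfg$baseline_sdlog))
    shift_dir <- if (h$direction == "early_to_late") 1 else -1
    if (si > 1 && n_shift > 0) {
      shift_scaled <- map_t(1 + h$shift) - map_t(1)
      peak[shifted_idx] <- pmin(pmax(
        peak[shifted_idx] + shift_dir * shift_scaled, 1), S)
    }
    mu <- vapply(t_grid, function(t) {
      bump_curve(t, peak, cfg$archetype_width, base, amp)
    }, numeric(length(peak)))

    n_rep <- sp$n_replicates
    cols <- as.vector(t(outer(seq_len(S), seq_len(n_rep), function(s, r) {
      sprintf("s%02d_r%d", s, r)
    })))
    lib <- if (cfg$libsize_sdlog > 0) {
      stats::rlnorm(S * n_rep, 0, cfg$libsize_sdlog)
    } else rep(1, S * n_rep)
    counts <- matrix(0, length(peak), S * n_rep,
                     dimnames = list(gene_ids, cols))
    col <- 0L
    for (s in seq_len(S)) {
      for (r in seq_len(n_rep)) {
        col <- col + 1L
        mcol <- mu[, s] * lib[col]
        counts[, col] <- if (cfg$dispersion > 0) {
          stats::rnbinom(length(mcol), mu = mcol, size = 1 / cfg$dispersion)
        } else mcol
      }
    }
    stage_labels <- sprintf("s%02d", seq_len(S))
    stage_info <- data.frame(
      stage = stage_labels, ordinal = seq_len(S),
      phase = ifelse(seq_len(S) <= sp$n_early, "pre-larval", "post-larval"),
      stringsAsFactors = FALSE)
    rep_map <- stats::setNames(lapply(seq_len(S), function(s) {
      sprintf("s%02d_r%d", s, seq_len(n_rep))
    }), stage_labels)
    tpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
    expression[[sp$name]] <- list(
      counts = expression_matrix(counts, sp$name, stage_info, "counts",
                                 replicate_map = rep_map),
      tpm = expression_matrix(tpm, sp$name, stage_info, "tpm",
                              replicate_map = rep_map))

    # labels: TF classes (planted enrichment in one archetype) and strata
    lb <- cfg$labels
    p_tf <- rep(lb$tf_fraction, length(gene_ids))
    p_tf[archetype == lb$enriched_archetype] <-
      min(1, lb$tf_fraction * lb$enrichment_factor)
    is_tf <- stats::runif(length(gene_ids)) < p_tf
    classes <- paste0("TF_class_",
                      formatC(sample.int(lb$n_tf_classes, sum(is_tf),
                                         replace = TRUE),
                              width = 2, flag = "0"))
    tf_classes <- stats::setNames(as.list(classes), gene_ids[is_tf])
    strata <- c(sample(lb$strata, n_orth, replace = TRUE,
                       prob = lb$strata_probs),
                rep("lineage-specific", n_spec))
    names(strata) <- gene_ids
    annotation[[sp$name]] <- gene_annotation(
      tf_classes = tf_classes, phylostratum = strata,
      strata_levels = lb$strata,
      catalogue = paste0("TF_class_",
                         formatC(seq_len(lb$n_tf_classes), width = 2,
                                 flag = "0")))
    truth_arch[[sp$name]] <- stats::setNames(archetype, gene_ids)
    gene_tables[[sp$name]] <- gene_ids[seq_len(n_orth)]
  }

  memberships <- lapply(seq_len(n_orth), function(i) {
    stats::setNames(lapply(species_names, function(sp) {
      gene_tables[[sp]][i]
    }), species_names)
  })
  names(memberships) <- og_ids
  map <- orthology_map(memberships)

  shifted <- data.frame(orthogroup = og_ids[shifted_idx],
                        stringsAsFactors = FALSE)
  for (sp in species_names) {
    shifted[[paste0("gene_", substr(sp, nchar(sp), nchar(sp)))]] <-
      gene_tables[[sp]][shifted_idx]
  }
  shifted$shift <- if (n_shift > 0) h$shift else integer(0)

  S_b <- cfg$species[[min(2, length(cfg$species))]]$n_stages
  correspondence <- data.frame(
    stage_a = sprintf("s%02d", seq_len(S_ref)),
    stage_b = sprintf("s%02d", round(1 + (seq_len(S_ref) - 1) *
                                       (S_b - 1) / (S_ref - 1))),
    stringsAsFactors = FALSE)

  truth <- structure(list(
    archetype = truth_arch, shifted = shifted,
    correspondence = correspondence,
    planted = list(tf_enriched_archetype = cfg$labels$enriched_archetype,
                   archetype_peaks = peaks)),
    class = "TruthBundle")

  structure(list(expression = expression, map = map,
                 annotation = annotation, truth = truth, config = cfg),
            class = "SyntheticBundle")
}

#' Write a synthetic bundle to disk
#'
#' Writes, per species, the counts and TPM tables (replicate columns
#' named `<stage>_r<j>`) and stage metadata, plus the Orthogroups.tsv
#' table, a long annotation table, the truth files, and a JSON manifest
#' recording the config and seed. All files use the TSV dialects the
#' package readers accept.
#'
#' @param bundle a `SyntheticBundle`.
#' @param dir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  assert_that(inherits(bundle, "SyntheticBundle"), "not a SyntheticBundle")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  assert_that(dir.exists(dir), paste0("cannot create directory ", dir))
  files <- character(0)
  for (sp in names(bundle$expression)) {
    for (layer in c("counts", "tpm")) {
      f <- file.path(dir, paste0(sp, "_", layer, ".tsv"))
      write_expression_table(bundle$expression[[sp]][[layer]], f)
      files <- c(files, f)
    }
    em <- bundle$expression[[sp]]$counts
    f <- file.path(dir, paste0(sp, "_stages.tsv"))
    utils::write.table(
      cbind(em$stage_info, species = sp,
            replicates = vapply(em$replicate_map[em$stage_info$stage],
                                paste, character(1), collapse = ",")),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    ann <- bundle$annotation[[sp]]
    long <- rbind(
      data.frame(gene = rep(names(ann$tf_classes),
                            vapply(ann$tf_classes, length, integer(1))),
                 label = unlist(ann$tf_classes, use.names = FALSE),
                 label_kind = "tf", stringsAsFactors = FALSE),
      data.frame(gene = names(ann$phylostratum),
                 label = unname(ann$phylostratum),
                 label_kind = "phylostratum", stringsAsFactors = FALSE))
    f <- file.path(dir, paste0(sp, "_annotation.tsv"))
    utils::write.table(long, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, "orthogroups.tsv")
  write_orthogroups(bundle$map, f)
  files <- c(files, f)
  f <- file.path(dir, "truth_shifted.tsv")
  utils::write.table(bundle$truth$shifted, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  manifest <- list(seed = bundle$config$seed,
                   config = unclass(bundle$config),
                   files = basename(files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a synthetic bundle back from disk
#'
#' @param dir directory written by [write_bundle()].
#' @return a list with `expression`, `map`, `config` fields mirroring the
#'   written bundle (truth and annotation reloaded when present).
#' @export
read_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  sp_spec <- manifest$config$species
  species <- if (is.data.frame(sp_spec)) sp_spec$name else
    vapply(sp_spec, `[[`, character(1), "name")
  expression <- list()
  for (sp in species) {
    st <- read_tsv_plain(file.path(dir, paste0(sp, "_stages.tsv")))
    rep_map <- stats::setNames(strsplit(st$replicates, ","), st$stage)
    layout <- function(layer) list(
      species_id = sp, layer = layer,
      stage_info = st[c("stage", "ordinal", "phase")],
      replicate_map = rep_map)
    expression[[sp]] <- list(
      counts = read_expression_table(
        file.path(dir, paste0(sp, "_counts.tsv")), layout("counts")),
      tpm = read_expression_table(
        file.path(dir, paste0(sp, "_tpm.tsv")), layout("tpm")))
  }
  list(expression = expression,
       map = read_orthogroups(file.path(dir, "orthogroups.tsv")),
       shifted = read_tsv_plain(file.path(dir, "truth_shifted.tsv")),
       config = manifest$config)
}
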
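#' Run configuration for the end-to-end pipeline
#'
#' Bundles the simulation (or input) config with the per-stage analysis
#' parameters.
#'
#' @param sim a `SimulationConfig` (synthetic input), or `NULL` together
#'   with `input_dir` to load a previously written bundle.
#' @param input_dir optional directory holding a bundle written by
#'   [write_bundle()].
#' @param k fixed cluster number; `NULL` selects k by the elbow rule over
#'   `k_range`.
#' @param k_range candidate k values for elbow selection.
#' @param fuzzifier fuzzifier m; `NULL` estimates it from the data.
#' @param restarts fuzzy c-means restarts.
#' @param bootstrap_B bootstrap replicates for the JSD grids.
#' @param jsd_scope `"global"` or `"per_comparison"` min-max scope.
#' @param direction heterochrony direction to extract
#'   (`"early_a_late_b"` or `"late_a_early_b"`).
#' @param correction multiple-testing method for enrichment tables.
#' @param seed root seed; per-stage seeds are derived from it.
#' @return a list of class `RunConfig`.
#' @export
run_config <- function(sim = simulation_config(), input_dir = NULL,
                       k = NULL, k_range = 2:8, fuzzifier = NULL,
                       restarts = 5L, bootstrap_B = 250L,
                       jsd_scope = "per_comparison",
                       direction = "early_a_late_b",
                       correction = "BH", seed = NULL) {
  structure(list(sim = sim, input_dir = input_dir, k = k,
                 k_range = k_range, fuzzifier = fuzzifier,
                 restarts = as.integer(restarts),
                 bootstrap_B = as.integer(bootstrap_B),
                 jsd_scope = jsd_scope, direction = direction,
                 correction = correction,
                 seed = as.integer(seed %||% sim$seed %||% 1L)),
            class = "RunConfig")
}

# Cluster one species: normalize counts, standardize, pick k, fit.
#' @keywords internal
#' @noRd
cluster_species <- function(counts, cfg, seed) {
  norm <- size_factor_normalize(counts)
  z <- standardize_profiles(norm, drop_unexpressed = TRUE)
  k <- cfg$k
  scan <- NULL
  if (is.null(k)) {
    scan <- min_centroid_distance(z, cfg$k_range, m = cfg$fuzzifier,
                                  seed = seed, restarts = cfg$restarts)
    k <- select_k_elbow(scan)
  }
  model <- fuzzy_cmeans(z, k, m = cfg$fuzzifier, seed = derive_seed(seed, 99),
                        restarts = cfg$restarts)
  list(z = z, model = model, scan = scan,
       assignments = harden_assignments(model))
}

#' Run the full comparative pipeline
#'
#' Executes simulate (or load) -> normalize -> cluster -> orthogroup
#' overlap (tests, quadrant RS, shifted gene sets) -> JSD stage matching
#' (bootstrap + normalization) -> enrichment, writing every result table
#' under `out_dir` with a header naming the producing version and seed,
#' plus a JSON manifest. With a fixed seed and single-threaded execution
#' two runs produce byte-identical outputs.
#'
#' @param cfg a `RunConfig`.
#' @param out_dir output directory.
#' @return (invisibly) a list with the in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir) {
  assert_that(inherits(cfg, "RunConfig"), "not a RunConfig")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  ver <- as.character(utils::packageVersion("devocomp"))
  hdr <- sprintf("devocomp %s seed=%d", ver, seed)
  manifest <- list(version = ver, seed = seed, stages = list())
  step <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  bundle <- step("simulate", {
    if (!is.null(cfg$input_dir)) {
      assert_that(dir.exists(cfg$input_dir),
                  paste0("missing input path: ", cfg$input_dir))
      stop("loading external bundles into the pipeline requires a ",
           "simulated truth; use the module functions directly")
    } else {
      b <- simulate_dataset(cfg$sim)
      write_bundle(b, file.path(out_dir, "data"))
      b
    }
  })
  species <- names(bundle$expression)
  assert_that(length(species) >= 2, "pipeline needs >= 2 species")
  sp_a <- species[[1]]
  sp_b <- species[[2]]

  clust <- step("cluster", {
    res <- lapply(seq_along(species), function(i) {
      cluster_species(bundle$expression[[species[i]]]$counts, cfg,
                      derive_seed(seed, i))
    })
    names(res) <- species
    for (sp in species) {
      write_tsv_fixed(res[[sp]]$assignments,
                      file.path(out_dir, paste0(sp, "_assignments.tsv")),
                      comment = hdr)
      cent <- data.frame(cluster = rownames(res[[sp]]$model$centroids),
                         res[[sp]]$model$centroids, check.names = FALSE)
      write_tsv_fixed(cent,
                      file.path(out_dir, paste0(sp, "_centroids.tsv")),
                      comment = hdr)
      if (!is.null(res[[sp]]$scan)) {
        write_tsv_fixed(res[[sp]]$scan,
                        file.path(out_dir, paste0(sp, "_dmin_vs_k.tsv")),
                        comment = hdr)
      }
    }
    res
  })

  overlap <- step("overlap", {
    sets_a <- to_orthogroup_sets(clust[[sp_a]]$assignments, bundle$map, sp_a)
    sets_b <- to_orthogroup_sets(clust[[sp_b]]$assignments, bundle$map, sp_b)
    universe <- length(intersect(unlist(sets_a), unlist(sets_b)))
    tab <- pairwise_overlap_tests(sets_a, sets_b, universe = universe,
                                  method = cfg$correction)
    q <- quadrant_spec_from_models(
      clust[[sp_a]]$model, clust[[sp_b]]$model,
      clust[[sp_a]]$z$stage_info, clust[[sp_b]]$z$stage_info)
    rs <- quadrant_relative_similarity(tab, q)
    shifted <- shifted_gene_sets(clust[[sp_a]]$assignments,
                                 clust[[sp_b]]$assignments,
                                 bundle$map, sp_a, sp_b, q,
                                 direction = cfg$direction)
    write_tsv_fixed(tab, file.path(out_dir, "overlap_table.tsv"),
                    comment = hdr)
    write_tsv_fixed(rs, file.path(out_dir, "quadrant_rs.tsv"),
                    comment = hdr)
    write_tsv_fixed(shifted, file.path(out_dir, "shifted_pairs.tsv"),
                    comment = hdr)
    list(table = tab, rs = rs, shifted = shifted, quadrants = q)
  })

  jsd <- step("jsd", {
    pairs <- one_to_one(bundle$map, sp_a, sp_b)
    qa <- quantile_transform(average_replicates(
      bundle$expression[[sp_a]]$tpm))
    qb <- quantile_transform(average_replicates(
      bundle$expression[[sp_b]]$tpm))
    grid <- bootstrap_jsd(qa, qb, pairs, B = cfg$bootstrap_B,
                          seed = derive_seed(seed, 41))
    grid <- normalize_jsd(grid, scope = cfg$jsd_scope)
    norm_grid <- grid$normalized %||% grid$relative
    for (nm in c("raw", "boot_mean", "boot_sd")) {
      write_tsv_fixed(data.frame(stage = rownames(grid[[nm]]), grid[[nm]],
                                 check.names = FALSE),
                      file.path(out_dir, paste0("jsd_", nm, ".tsv")),
                      comment = hdr)
    }
    write_tsv_fixed(data.frame(stage = rownames(norm_grid), norm_grid,
                               check.names = FALSE),
                    file.path(out_dir, "jsd_normalized.tsv"),
                    comment = hdr)
    list(grid = grid, pairs = pairs)
  })

  enrich <- step("enrich", {
    res <- lapply(c("tf", "phylostratum"), function(kind) {
      tab <- label_enrichment(clust[[sp_a]]$assignments,
                              bundle$annotation[[sp_a]],
                              label_kind = kind,
                              correction = cfg$correction)
      write_tsv_fixed(tab,
                      file.path(out_dir,
                                paste0(sp_a, "_enrichment_", kind, ".tsv")),
                      comment = hdr)
      tab
    })
    names(res) <- c("tf", "phylostratum")
    qn <- quantile_normalize(average_replicates(
      size_factor_normalize(bundle$expression[[sp_a]]$counts)))
    prof <- phylostratum_profile(qn, bundle$annotation[[sp_a]])
    write_tsv_fixed(prof,
                    file.path(out_dir,
                              paste0(sp_a, "_phylostratum_profile.tsv")),
                    comment = hdr)
    res$profile <- prof
    res
  })

  manifest$outputs <- sort(list.files(out_dir, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(bundle = bundle, clusters = clust, overlap = overlap,
                 jsd = jsd, enrichment = enrich, manifest = manifest))
}
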
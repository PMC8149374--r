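# End-to-end orchestration: simulate -> preprocess -> unmix (TCA) -> extract
# ROI spectra -> PCA (+ per-animal statistics) -> sparse MCR (+ per-map
# abundance statistics), with warm-start transfer of MCR components from one
# cohort to the next (the murine -> human design).

#' Gated group comparison (two or more groups)
#'
#' Dispatches to [compare_two_groups()] or [compare_multi_groups()] by the
#' number of groups in the table.
#'
#' @inheritParams compare_two_groups
#' @return A `test_report`.
#' @export
compare_groups <- function(table, alpha = 0.05, welch = FALSE,
                           force = c("auto", "parametric", "nonparametric")) {
  force <- match.arg(force)
  table <- as_group_table(table)
  if (length(unique(table$group)) == 2) {
    compare_two_groups(table, alpha, welch, force)
  } else {
    compare_multi_groups(table, alpha, welch, force)
  }
}

#' Default pipeline configuration
#'
#' The demo design: a murine cohort (WT, Fbln5KO, Fbln4SMKO ascending aortas,
#' 6 maps each — the aneurysm genotype carries the two disease-only
#' components) and a human cohort (3 control, 3 aTAA) whose MCR is
#' warm-started from the murine components. High-resolution scan geometry
#' (10 x 150 pixels at 1 um), axis 300-2000 cm^-1 step 2 so that fingerprint
#' cropping is exercised, penalty 0.002, 16 elastic / 12 collagen MCR
#' components, alpha 0.05.
#'
#' @return Nested configuration list accepted by [run_all()].
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    simulate = list(
      axis = c(300, 2000, 2),
      scan_kind = "high_res",
      noise = list(gaussian_sd = 0.01, shot_scale = 0.01, spike_rate = 5),
      disease_level = 0.6
    ),
    cohorts = list(
      murine = list(
        species = "mouse", region = "ascending",
        groups = list(
          list(name = "WT", n_maps = 6),
          list(name = "Fbln5KO", n_maps = 6),
          list(name = "Fbln4SMKO", n_maps = 6,
               disease_components = c("ce1_like", "cc6_like"))
        )
      ),
      human = list(
        species = "human", region = "ascending",
        warm_start_from = "murine", k_extra = 2,
        groups = list(
          list(name = "human_control", n_maps = 3),
          list(name = "aTAA", n_maps = 3,
               disease_components = c("ce1_like", "cc6_like"))
        )
      )
    ),
    preprocess = list(z_threshold = 8, window = 5, als_lambda = 1e5,
                      als_p = 0.001, n_iter = 10, crop = c(400, 1800)),
    tca = list(references = c("elastic_fiber", "collagen_fiber", "nuclei",
                              "aggrecan", "versican", "lipid",
                              "residual_ecm"),
               n_free = 0, roi_quantile = 0.6, max_roi_per_map = 150),
    pca = list(k = 6),
    mcr = list(lam = 0.002, k_elastic = 16, k_collagen = 12,
               tol = 1e-8, max_iter = 150),
    stats = list(alpha = 0.05)
  )
}

merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(override[[nm]])) && nm != "cohorts" &&
        nm != "groups") {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

validate_run_config <- function(cfg) {
  fail <- function(msg) rm_abort(paste0("config: ", msg), "config")
  ax <- cfg$simulate$axis
  if (length(ax) != 3 || ax[1] >= ax[2] || ax[3] <= 0) {
    fail("simulate$axis must be c(lo, hi, step) with lo < hi")
  }
  if (!cfg$simulate$scan_kind %in% c("large_area", "high_res")) {
    fail(sprintf("unknown scan_kind '%s'", cfg$simulate$scan_kind))
  }
  if (!length(cfg$cohorts)) fail("no cohorts defined")
  known <- names(builtin_band_tables())
  for (cn in names(cfg$cohorts)) {
    co <- cfg$cohorts[[cn]]
    nms <- vapply(co$groups, function(g) g$name %||% "", character(1))
    if (any(!nzchar(nms)) || anyDuplicated(nms)) {
      fail(sprintf("cohort '%s': group names must be unique and non-empty",
                   cn))
    }
    for (g in co$groups) {
      if ((g$n_maps %||% 0) < 1) {
        fail(sprintf("group '%s' needs n_maps >= 1", g$name))
      }
      bad <- setdiff(g$disease_components %||% character(0), known)
      if (length(bad)) {
        fail(sprintf("group '%s': unknown component(s) %s", g$name,
                     paste(bad, collapse = ", ")))
      }
    }
    ws <- co$warm_start_from
    if (!is.null(ws) &&
        !ws %in% names(cfg$cohorts)[seq_len(match(cn, names(cfg$cohorts)) -
                                              1)]) {
      fail(sprintf("cohort '%s' warm-starts from '%s', which is not an
 earlier cohort", cn, ws))
    }
  }
  bad_ref <- setdiff(cfg$tca$references, known)
  if (length(bad_ref)) {
    fail(sprintf("unknown TCA reference(s): %s",
                 paste(bad_ref, collapse = ", ")))
  }
  if (cfg$stats$alpha <= 0 || cfg$stats$alpha >= 1) {
    fail("stats$alpha must be in (0, 1)")
  }
  invisible(cfg)
}

fiber_settings <- function(cfg) {
  list(
    elastic_fiber = list(k = cfg$mcr$k_elastic, disease_ref = "ce1_like",
                         label = "Ce"),
    collagen_fiber = list(k = cfg$mcr$k_collagen, disease_ref = "cc6_like",
                          label = "Cc")
  )
}

process_cohort <- function(cname, cfg, axis, warm_bases) {
  co <- cfg$cohorts[[cname]]
  pp_cfg <- cfg$preprocess
  groups <- lapply(co$groups, function(g) {
    g$species <- g$species %||% co$species %||% "mouse"
    g$region <- g$region %||% co$region %||% "ascending"
    g$disease_level <- g$disease_level %||% cfg$simulate$disease_level
    g
  })
  noise <- do.call(noise_model, cfg$simulate$noise)
  cohort_offset <- match(cname, names(cfg$cohorts)) * 104729
  design <- cohort_design(groups, scan_kind = cfg$simulate$scan_kind,
                          noise = noise, seed = cfg$seed + cohort_offset,
                          axis = axis)
  sims <- simulate_cohort(design)

  pp <- lapply(sims, function(s) {
    preprocess_map(s$map, z_threshold = pp_cfg$z_threshold,
                   window = pp_cfg$window, als_lambda = pp_cfg$als_lambda,
                   als_p = pp_cfg$als_p, n_iter = pp_cfg$n_iter,
                   crop_lo = pp_cfg$crop[1], crop_hi = pp_cfg$crop[2])
  })
  maps <- lapply(pp, `[[`, "map")
  axis_pp <- maps[[1]]$wavenumber
  refs <- reference_library(axis_pp, cfg$tca$references)

  tcas <- lapply(maps, fit_tca, references = refs, n_free = cfg$tca$n_free)
  map_group <- vapply(maps, function(m) m$meta$group, character(1))
  map_animal <- vapply(maps, function(m) m$meta$animal_id, character(1))

  fibers <- fiber_settings(cfg)
  fiber_results <- list()
  for (fiber in names(fibers)) {
    fs <- fibers[[fiber]]
    ds <- bind_datasets(lapply(seq_along(maps), function(i) {
      roi <- extract_roi_spectra(maps[[i]], tcas[[i]], fiber,
                                 q = cfg$tca$roi_quantile)
      n_max <- cfg$tca$max_roi_per_map %||% Inf
      if (nrow(roi$spectra) > n_max) {
        keep <- with_seed(cfg$seed + 31L * i,
                          sort(sample.int(nrow(roi$spectra), n_max)))
        roi <- spectral_dataset(roi$wavenumber,
                                roi$spectra[keep, , drop = FALSE],
                                roi$labels[keep, , drop = FALSE])
      }
      roi
    }))

    pca <- fit_pca_nipals(ds, cfg$pca$k)
    pca_stats <- lapply(seq_len(cfg$pca$k), function(pc) {
      am <- animal_mean_scores(pca, pc)
      compare_groups(group_table(am$animal_id, am$group, am$mean_score),
                     alpha = cfg$stats$alpha)
    })

    A <- t(ds$spectra)
    base <- warm_bases[[fiber]]
    if (!is.null(co$warm_start_from) && !is.null(base)) {
      mcr <- warm_start_fit(A, base, k_extra = co$k_extra %||% 0,
                            lam = cfg$mcr$lam, tol = cfg$mcr$tol,
                            max_iter = cfg$mcr$max_iter)
    } else {
      mcr <- fit_mcr_als(A, fs$k, lam = cfg$mcr$lam, tol = cfg$mcr$tol,
                         max_iter = cfg$mcr$max_iter,
                         names = sprintf("%s%02d", fs$label,
                                         seq_len(fs$k)))
    }

    # name the aneurysm-analog and native-fiber components by cosine match
    probe <- reference_library(axis_pp, c(fiber, fs$disease_ref))
    pm <- match_components(mcr$W, probe)
    native_idx <- pm$assignment[1]
    disease_idx <- pm$assignment[2]

    means <- mean_abundance_per_map(mcr, ds$labels$animal_id)
    comp_names <- rownames(mcr$H)
    abund_stats <- lapply(
      c(native = native_idx, disease = disease_idx), function(idx) {
        sel <- means[means$component == comp_names[idx], ]
        gt <- group_table(sel$map_id,
                          map_group[match(sel$map_id, map_animal)],
                          sel$mean_intensity)
        compare_groups(gt, alpha = cfg$stats$alpha)
      })

    fiber_results[[fiber]] <- list(
      dataset = ds, pca = pca, pca_stats = pca_stats, mcr = mcr,
      match = pm, native_component = comp_names[native_idx],
      disease_component = comp_names[disease_idx],
      disease_match_cosine = unname(pm$matched_cosine[2]),
      abundance_means = means, abundance_stats = abund_stats)
  }

  list(name = cname, design = design, maps = maps, tcas = tcas,
       n_spikes_removed = vapply(pp, `[[`, integer(1), "n_spikes_removed"),
       map_group = map_group, map_animal = map_animal,
       fibers = fiber_results)
}

#' Run the full analysis pipeline
#'
#' Deterministic given `config$seed`: simulates every cohort, preprocesses
#' all maps, unmixes against the reference library, extracts elastic- and
#' collagen-fiber ROI datasets, runs NIPALS PCA with per-animal score
#' statistics, fits sparse MCR-ALS (warm-started across cohorts where
#' configured), and compares per-map mean abundances of the matched native
#' and disease components between groups.
#'
#' @param config `NULL` (defaults), a nested list overriding
#'   [default_run_config()], or the path of a YAML file with the same
#'   structure.
#' @param out_dir Optional output directory; when given, scores, loadings,
#'   abundance means, component spectra, statistics reports, heatmaps and a
#'   run manifest are written there.
#' @return A results bundle: `config`, per-cohort results (`cohorts`), and
#'   `manifest`.
#' @export
run_all <- function(config = NULL, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_run_config(), config)
  validate_run_config(cfg)
  axis <- seq(cfg$simulate$axis[1], cfg$simulate$axis[2],
              by = cfg$simulate$axis[3])

  cohort_results <- list()
  warm_bases <- list()
  for (cname in names(cfg$cohorts)) {
    co <- cfg$cohorts[[cname]]
    bases <- if (!is.null(co$warm_start_from)) {
      prev <- cohort_results[[co$warm_start_from]]
      lapply(prev$fibers, function(f) {
        component_set(prev$maps[[1]]$wavenumber, f$mcr$W,
                      colnames(f$mcr$W), fixed = FALSE)
      })
    } else {
      list()
    }
    res <- process_cohort(cname, cfg, axis, bases)
    cohort_results[[cname]] <- res
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ramanmark")),
    seed = cfg$seed,
    config = cfg,
    cohorts = lapply(cohort_results, function(r) {
      list(n_maps = length(r$maps),
           groups = as.list(table(r$map_group)),
           n_spikes_removed = sum(r$n_spikes_removed),
           disease_components = lapply(r$fibers, `[[`, "disease_component"))
    })
  )
  bundle <- list(config = cfg, cohorts = cohort_results, manifest = manifest)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

report_to_list <- function(rep) {
  list(test = rep$test_name, statistic = rep$statistic, p_value = rep$p_value,
       comparisons = rep$comparisons, normality = rep$normality)
}

write_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (cname in names(bundle$cohorts)) {
    r <- bundle$cohorts[[cname]]
    cdir <- file.path(out_dir, cname)
    dir.create(cdir, showWarnings = FALSE, recursive = TRUE)
    # TCA heatmaps for the first map of each group
    first_idx <- match(unique(r$map_group), r$map_group)
    for (i in first_idx) {
      render_heatmaps(r$tcas[[i]]$abundances,
                      file.path(cdir, "tca_heatmaps"),
                      prefix = paste0(r$map_group[i], "_"))
    }
    for (fiber in names(r$fibers)) {
      f <- r$fibers[[fiber]]
      stem <- file.path(cdir, fiber)
      utils::write.csv(cbind(f$pca$labels,
                             as.data.frame(f$pca$scores)),
                       paste0(stem, "_pca_scores.csv"), row.names = FALSE)
      utils::write.csv(as.data.frame(t(f$pca$loadings)),
                       paste0(stem, "_pca_loadings.csv"), row.names = FALSE)
      utils::write.csv(f$abundance_means, paste0(stem, "_mcr_means.csv"),
                       row.names = FALSE)
      W <- f$mcr$W
      utils::write.csv(data.frame(wavenumber = r$maps[[1]]$wavenumber, W),
                       paste0(stem, "_mcr_components.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(native_component = f$native_component,
             disease_component = f$disease_component,
             disease_match_cosine = f$disease_match_cosine,
             native = report_to_list(f$abundance_stats$native),
             disease = report_to_list(f$abundance_stats$disease),
             pca = lapply(f$pca_stats, report_to_list)),
        paste0(stem, "_stats.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
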
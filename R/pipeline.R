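# End-to-end pipeline: generate (or read) plot scenes, extract RGB indices
# at ground and emulated-aerial resolution, summarise band stacks,
# correlate everything against yield and leaf phosphorus, and fit forward
# stepwise yield models. All outputs are plain CSV/JSON under one output
# directory; a rerun with the same config and seed is bit-identical.

RGB_INDEX_COLUMNS <- c("intensity", "hue_deg", "saturation", "lightness",
                       "a_star", "b_star", "u_star", "v_star", "ga", "gga")

#' Configuration of one pipeline run
#'
#' @param out_dir Output directory (created; contents overwritten).
#' @param mode `"synthetic"` (generate a trial) or `"directory"` (read
#'   per-plot images and a plot table from `input_dir`).
#' @param seed Integer seed driving all randomness in the run.
#' @param design A [trial_design()] for synthetic mode; its seed is
#'   replaced by `seed`.
#' @param input_dir Directory for `"directory"` mode; must contain
#'   `plots.csv` (columns `plot_id`, `treatment`, `grain_yield`, optional
#'   `genotype`, `leaf_p`, `image`, `bands_manifest`) and the referenced
#'   image files (default `<plot_id>.png`).
#' @param savi_L SAVI soil-adjustment factor.
#' @param aggregation Spectral aggregation mode, `"mean-reflectance"` or
#'   `"per-pixel-mean"`.
#' @param downsample_factor Integer block size for aerial emulation.
#' @param alpha_enter Stepwise entry threshold.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, mode = c("synthetic", "directory"), seed = 1L,
                       design = trial_design(), input_dir = NULL,
                       savi_L = 0.5,
                       aggregation = c("mean-reflectance", "per-pixel-mean"),
                       downsample_factor = AERIAL_DOWNSAMPLE_FACTOR,
                       alpha_enter = 0.05) {
  mode <- match.arg(mode)
  aggregation <- match.arg(aggregation)
  if (mode == "directory" && is.null(input_dir)) {
    stop("directory mode needs input_dir", call. = FALSE)
  }
  design$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, mode = mode, seed = as.integer(seed),
                 design = design, input_dir = input_dir, savi_L = savi_L,
                 aggregation = aggregation,
                 downsample_factor = as.integer(downsample_factor),
                 alpha_enter = alpha_enter),
            class = "run_config")
}

# Read the plot table and images of a directory-mode run. Unreadable plots
# are skipped with a reason.
.load_directory <- function(input_dir, log) {
  tab_path <- file.path(input_dir, "plots.csv")
  if (!file.exists(tab_path)) stop("plots.csv not found in input_dir", call. = FALSE)
  tab <- utils::read.csv(tab_path, stringsAsFactors = FALSE)
  stopifnot(all(c("plot_id", "treatment", "grain_yield") %in% names(tab)))
  scenes <- list(); keep <- logical(nrow(tab)); skipped <- character(0)
  for (i in seq_len(nrow(tab))) {
    id <- tab$plot_id[i]
    img_file <- if ("image" %in% names(tab) && nzchar(tab$image[i])) tab$image[i]
                else paste0(id, ".png")
    res <- tryCatch({
      img <- read_rgb_image(file.path(input_dir, img_file), plot_id = id)
      stack <- NULL
      if ("bands_manifest" %in% names(tab) && !is.na(tab$bands_manifest[i]) &&
          nzchar(tab$bands_manifest[i])) {
        stack <- read_band_stack(file.path(input_dir, tab$bands_manifest[i]),
                                 plot_id = id)
      }
      list(rgb = img, stack = stack, truth = NULL)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      log(sprintf("skip plot %s: %s", id, conditionMessage(res)))
      skipped <- c(skipped, id)
    } else {
      keep[i] <- TRUE
      scenes[[id]] <- res
    }
  }
  list(records = tab[keep, , drop = FALSE], scenes = scenes, skipped = skipped)
}

#' Run the full phenotyping pipeline
#'
#' Executes generate/read -> ground RGB indices -> aerial emulation ->
#' spectral summaries -> treatment ANOVA -> correlation tables -> forward
#' stepwise models, writing all artifacts under `config$out_dir`:
#' `index_table.csv` (one row per plot with ground/aerial RGB indices and
#' spectral indices), `ground_vs_aerial.csv` (per-index Pearson r between
#' platforms), `correlations_yield.csv` and `correlations_leafp.csv`
#' (grouped correlation tables), `stepwise_report.csv`, `manifest.json`
#' (all parameters, seed and skip counts) and `run.log`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the index table, the comparison and
#'   correlation tables, the stepwise results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, msg)
  log(sprintf("mode=%s seed=%d savi_L=%g aggregation=%s factor=%d alpha=%g",
              config$mode, config$seed, config$savi_L, config$aggregation,
              config$downsample_factor, config$alpha_enter))

  skipped <- character(0)
  if (config$mode == "synthetic") {
    trial <- generate_trial(config$design, render = TRUE)
    records <- trial$records
    scenes <- trial$scenes
  } else {
    loaded <- .load_directory(config$input_dir, log)
    records <- loaded$records
    scenes <- loaded$scenes
    skipped <- loaded$skipped
  }
  log(sprintf("%d plots loaded, %d skipped", length(scenes), length(skipped)))

  rows <- vector("list", length(scenes))
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    ground <- summarize_rgb_plot(sc$rgb)
    names(ground) <- paste0("ground_", names(ground))
    aerial <- summarize_rgb_plot(degrade_resolution(sc$rgb,
                                                    config$downsample_factor))
    names(aerial) <- paste0("aerial_", names(aerial))
    row <- cbind(ground, aerial)
    if (!is.null(sc$stack)) {
      spec <- summarize_spectral_plot(sc$stack, mode = config$aggregation,
                                      L = config$savi_L)
      row <- cbind(row, spec[, setdiff(names(spec), c("plot_id", "mode"))])
    }
    rows[[i]] <- cbind(plot_id = names(scenes)[i], row,
                       stringsAsFactors = FALSE)
  }
  idx <- do.call(rbind, rows)
  table_out <- merge(records, idx, by = "plot_id", sort = TRUE)
  table_out <- table_out[order(table_out$plot_id), , drop = FALSE]
  write_index_table(table_out, file.path(config$out_dir, "index_table.csv"))

  # ground vs aerial agreement per RGB index
  gva <- data.frame(index = RGB_INDEX_COLUMNS, r = NA_real_, p = NA_real_)
  for (i in seq_len(nrow(gva))) {
    g <- table_out[[paste0("ground_", gva$index[i])]]
    a <- table_out[[paste0("aerial_", gva$index[i])]]
    ok <- !is.na(g) & !is.na(a)
    if (sum(ok) >= 3L && stats::sd(g[ok]) > 0 && stats::sd(a[ok]) > 0) {
      ct <- stats::cor.test(g[ok], a[ok])
      gva$r[i] <- unname(ct$estimate); gva$p[i] <- ct$p.value
    }
  }
  write_index_table(gva, file.path(config$out_dir, "ground_vs_aerial.csv"))

  spectral_cols <- intersect(c(SPECTRAL_INDEX_NAMES,
                               paste0("b", SPECTRAL_WAVELENGTHS)),
                             names(table_out))
  rgb_cols <- c(paste0("ground_", RGB_INDEX_COLUMNS),
                paste0("aerial_", RGB_INDEX_COLUMNS))
  index_cols <- c(rgb_cols, spectral_cols)

  cor_y <- pearson_table(table_out, index_cols, "grain_yield")
  write_index_table(cor_y, file.path(config$out_dir, "correlations_yield.csv"))
  cor_p <- NULL
  if ("leaf_p" %in% names(table_out)) {
    cor_p <- pearson_table(table_out, index_cols, "leaf_p")
    write_index_table(cor_p, file.path(config$out_dir, "correlations_leafp.csv"))
  }

  # forward stepwise yield (and leaf P) models per predictor family and arm
  aerial_vis <- paste0("aerial_", RGB_INDEX_COLUMNS)
  spectral_vis <- intersect(SPECTRAL_INDEX_NAMES, names(table_out))
  models <- list()
  responses <- c(grain_yield = "grain_yield",
                 leaf_p = if ("leaf_p" %in% names(table_out)) "leaf_p" else NULL)
  for (resp in responses) {
    for (arm in unique(records$treatment)) {
      sub <- table_out[table_out$treatment == arm, , drop = FALSE]
      for (fam in c("aerial_rgb", "multispectral")) {
        cand <- if (fam == "aerial_rgb") aerial_vis else spectral_vis
        if (length(cand) == 0L) next
        res <- tryCatch(
          forward_stepwise(sub, resp, cand, alpha_enter = config$alpha_enter),
          error = function(e) e)
        if (inherits(res, "error")) {
          log(sprintf("stepwise %s/%s/%s failed: %s", resp, arm, fam,
                      conditionMessage(res)))
          next
        }
        models[[sprintf("%s.%s.%s", resp, arm, fam)]] <- res
      }
    }
  }
  step_rows <- list()
  for (nm in names(models)) {
    m <- models[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    terms <- if (m$intercept_only) "(Intercept)" else c("(Intercept)", m$terms)
    for (tm in terms) {
      step_rows[[length(step_rows) + 1L]] <- data.frame(
        response = parts[1L], arm = parts[2L], predictor_set = parts[3L],
        term = tm, coefficient = unname(m$coefficients[tm]),
        r_squared = m$r_squared, rse = m$rse, model_p = m$model_p,
        portion = if (tm == "(Intercept)") NA_real_ else unname(m$portions[tm]),
        n = m$n, stringsAsFactors = FALSE)
    }
  }
  step_tab <- if (length(step_rows)) do.call(rbind, step_rows) else
    data.frame(response = character(0))
  write_index_table(step_tab, file.path(config$out_dir, "stepwise_report.csv"))

  # treatment ANOVA across available traits
  anova_traits <- intersect(c("grain_yield", "leaf_p", "lcc", "n_pct", "c_pct",
                              "cn_ratio", "d13c", "d15n"), names(table_out))
  anova_rows <- lapply(anova_traits, function(tr) {
    a <- tryCatch(treatment_anova(table_out, tr), error = function(e) NULL)
    if (is.null(a)) return(NULL)
    data.frame(trait = tr, F = a$F, p = a$p,
               stars = significance_stars(a$p),
               t(stats::setNames(a$means$mean, paste0("mean_", a$means$level))),
               t(stats::setNames(a$means$se, paste0("se_", a$means$level))))
  })
  anova_tab <- do.call(rbind, anova_rows)
  if (!is.null(anova_tab)) {
    write_index_table(anova_tab, file.path(config$out_dir, "treatment_anova.csv"))
  }

  manifest <- list(
    mode = config$mode, seed = config$seed, savi_L = config$savi_L,
    aggregation = config$aggregation,
    downsample_factor = config$downsample_factor,
    alpha_enter = config$alpha_enter,
    n_plots = nrow(table_out), n_skipped = length(skipped),
    skipped = as.list(skipped),
    design = if (config$mode == "synthetic")
      config$design[setdiff(names(config$design), c("trait_means", "trait_sds"))]
      else NULL)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(config$out_dir, "run.log"))

  invisible(list(index_table = table_out, ground_vs_aerial = gva,
                 correlations_yield = cor_y, correlations_leafp = cor_p,
                 stepwise = models, anova = anova_tab, manifest = manifest))
}
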
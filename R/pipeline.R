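#' Batch-run configuration
#'
#' Ties the preprocessing chain, the metrics and the statistical layer into
#' one reproducible run: which meshes, which metadata, which tunables,
#' where to write. The metadata CSV must have columns `mesh_id`,
#' `individual_id`, `species`, `sex`, `side`; `mesh_id` is the mesh file
#' name without extension.
#'
#' @param meshes character vector of mesh paths, or a glob pattern.
#' @param metadata path to the metadata CSV, or a data frame.
#' @param config a [topo_config].
#' @param output_dir directory for CSV/PLY/PNG outputs (created if needed).
#' @param preprocess run clean/decimate/smooth on each mesh before metrics.
#' @param estimator model estimator for [run_analysis].
#' @param export_maps write per-face/vertex metric maps as PLY.
#' @param seed global seed for simulation utilities (metric computation
#'   itself is RNG-free).
#' @return an object of class `run_config`.
#' @export
run_config <- function(meshes, metadata, config = topo_config(),
                       output_dir = ".", preprocess = TRUE,
                       estimator = c("random_intercept", "ols"),
                       export_maps = FALSE, seed = 1L) {
  estimator <- match.arg(estimator)
  if (length(meshes) == 1L && grepl("[*?]", meshes))
    meshes <- Sys.glob(meshes)
  if (length(meshes) == 0L) stop("empty manifest: no meshes")
  md <- if (is.character(metadata)) utils::read.csv(metadata) else as.data.frame(metadata)
  need <- c("mesh_id", "individual_id", "species", "sex", "side")
  if (!all(need %in% names(md)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  ids <- tools::file_path_sans_ext(basename(meshes))
  missing_md <- setdiff(ids, md$mesh_id)
  if (length(missing_md))
    stop("meshes without metadata rows: ", paste(missing_md, collapse = ", "))
  structure(list(meshes = meshes, mesh_ids = ids, metadata = md,
                 config = config, output_dir = output_dir,
                 preprocess = preprocess, estimator = estimator,
                 export_maps = export_maps, seed = as.integer(seed)),
            class = "run_config")
}

#' Compute the metrics table for a batch of meshes
#'
#' One row per mesh: the six metrics, face counts before/after
#' preprocessing and the config hash. Per-mesh failures are logged and
#' skipped, not fatal. Deterministic given meshes + config.
#'
#' @param rc a [run_config].
#' @return data frame (also written to `metrics.csv` in the output dir);
#'   skipped meshes are recorded in the `skipped` attribute.
#' @export
run_metrics <- function(rc) {
  if (!inherits(rc, "run_config")) stop("expected a 'run_config'")
  dir.create(rc$output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(rc$config)
  rows <- list(); skipped <- character(0)
  for (i in seq_along(rc$meshes)) {
    id <- rc$mesh_ids[i]
    t0 <- proc.time()[["elapsed"]]
    row <- tryCatch({
      mesh <- read_mesh(rc$meshes[i])
      faces_in <- nrow(mesh$faces)
      res <- topography(mesh, rc$config, preprocess = rc$preprocess)
      if (rc$export_maps) {
        mm <- if (rc$preprocess) {
          m2 <- clean_mesh(mesh, rc$config)
          m2 <- decimate(m2, rc$config$decimate_target)
          taubin_smooth(m2, rc$config$taubin_lambda, rc$config$taubin_mu,
                        rc$config$taubin_iters)
        } else mesh
        write_mesh(mm, file.path(rc$output_dir, paste0(id, "_maps.ply")),
                   vertex_scalars = list(pcv = res$vertex_pcv),
                   face_scalars = list(
                     # DNE signed by the convex/concave label, map style
                     dne_signed = res$face_dne *
                       ifelse(res$face_convex, 1, -1),
                     opc_bin = as.numeric(res$face_opc_bin)))
      }
      cbind(data.frame(mesh_id = id), as.data.frame(res),
            data.frame(faces_in = faces_in, config_hash = hash))
    }, error = function(e) {
      message(sprintf("[%s] skipped: %s", id, conditionMessage(e)))
      NULL
    })
    message(sprintf("[%s] %s in %.2fs", id,
                    if (is.null(row)) "FAILED" else "ok",
                    proc.time()[["elapsed"]] - t0))
    if (is.null(row)) skipped <- c(skipped, id) else rows[[id]] <- row
  }
  if (!length(rows)) stop("every mesh failed")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, file.path(rc$output_dir, "metrics.csv"),
                   row.names = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Run the statistical analysis over a metrics table
#'
#' Joins metadata, then emits the full report bundle: descriptive
#' statistics by species x sex x side, paired (side) and unpaired (sex)
#' exact rank tests with effect sizes, Pearson matrices for the full sample
#' and per-species subsets, and the 8-model AICc selection per metric, plus
#' simple per-metric group plots with left-right lines per individual.
#'
#' @param metrics_table data frame from [run_metrics] (needs `mesh_id`).
#' @param rc a [run_config] (metadata, estimator, output dir).
#' @param metrics metric columns to analyse.
#' @return invisible list with components `descriptives`, `side_tests`,
#'   `sex_tests`, `correlations`, `model_selection`, `best_models`; all
#'   also written as CSVs to the output directory.
#' @export
run_analysis <- function(metrics_table, rc,
                         metrics = c("dne", "rfi", "opcr", "pcv",
                                     "sa3d", "oa2d")) {
  if (!inherits(rc, "run_config")) stop("expected a 'run_config'")
  dir.create(rc$output_dir, showWarnings = FALSE, recursive = TRUE)
  df <- merge(metrics_table, rc$metadata, by = "mesh_id")
  if (nrow(df) == 0L) stop("no rows after metadata join")

  # descriptives (sample sd, the R default; population flag recorded)
  cells <- expand.grid(species = unique(df$species),
                       sex = c(unique(df$sex), "both"),
                       side = c(unique(df$side), "both"),
                       stringsAsFactors = FALSE)
  desc <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- df$species == cells$species[i] &
      (cells$sex[i] == "both" | df$sex == cells$sex[i]) &
      (cells$side[i] == "both" | df$side == cells$side[i])
    if (!any(sel)) return(NULL)
    row <- data.frame(species = cells$species[i], sex = cells$sex[i],
                      side = cells$side[i], n = sum(sel), sd_type = "sample")
    for (m in metrics) {
      row[[paste0(m, "_mean")]] <- mean(df[[m]][sel])
      row[[paste0(m, "_sd")]] <- stats::sd(df[[m]][sel])
    }
    row
  }))
  utils::write.csv(desc, file.path(rc$output_dir, "descriptives.csv"),
                   row.names = FALSE)

  # paired side tests: one difference per individual with both sides
  side_tests <- do.call(rbind, lapply(metrics, function(m) {
    wide <- merge(df[df$side == "L", c("individual_id", m)],
                  df[df$side == "R", c("individual_id", m)],
                  by = "individual_id", suffixes = c("_L", "_R"))
    if (nrow(wide) < 2L) return(NULL)
    dd <- wide[[paste0(m, "_L")]] - wide[[paste0(m, "_R")]]
    tst <- tryCatch(signed_rank_exact(dd), error = function(e) NULL)
    if (is.null(tst)) return(NULL)
    ef <- effect_sizes(wide[[paste0(m, "_L")]], wide[[paste0(m, "_R")]],
                       paired = TRUE)
    data.frame(comparison = "side", metric = m, n = tst$n,
               statistic = tst$statistic, p = tst$p_two_sided,
               method = tst$method, cohens_d = ef$cohens_d_pooled,
               cohens_d_paired = ef$cohens_d_paired, rank_r = ef$rank_r)
  }))
  if (!is.null(side_tests))
    utils::write.csv(side_tests, file.path(rc$output_dir, "side_tests.csv"),
                     row.names = FALSE)

  # unpaired sex tests within each side (skip if a group is empty)
  sexes <- unique(df$sex)
  sex_tests <- NULL
  if (length(sexes) == 2L) {
    sex_tests <- do.call(rbind, lapply(metrics, function(m) {
      do.call(rbind, lapply(unique(df$side), function(sd_) {
        a <- df[[m]][df$sex == sexes[1L] & df$side == sd_]
        b <- df[[m]][df$sex == sexes[2L] & df$side == sd_]
        if (length(a) < 2L || length(b) < 2L) return(NULL)
        tst <- mann_whitney_exact(a, b)
        ef <- effect_sizes(a, b)
        data.frame(comparison = paste0("sex(", sd_, ")"), metric = m,
                   n1 = tst$n1, n2 = tst$n2, statistic = tst$statistic,
                   p = tst$p_two_sided, method = tst$method,
                   cohens_d = ef$cohens_d_pooled, rank_r = ef$rank_r)
      }))
    }))
    if (!is.null(sex_tests))
      utils::write.csv(sex_tests, file.path(rc$output_dir, "sex_tests.csv"),
                       row.names = FALSE)
  } else {
    warning("sex comparison skipped: need exactly 2 sexes, found ",
            length(sexes))
  }

  # Pearson matrices: full sample + per species
  cors <- list(all = pearson_matrix(df, metrics))
  for (sp in unique(df$species)) {
    sub <- df[df$species == sp, , drop = FALSE]
    if (sum(stats::complete.cases(sub[metrics])) >= 3L)
      cors[[sp]] <- pearson_matrix(sub, metrics)
  }
  for (nm in names(cors))
    utils::write.csv(round(cors[[nm]], 6),
                     file.path(rc$output_dir,
                               paste0("pearson_", gsub("\\W", "_", nm), ".csv")))

  # model family per metric
  msel <- list(); best <- list()
  for (m in metrics) {
    fam <- tryCatch(fit_model_family(df, m, estimator = rc$estimator),
                    error = function(e) NULL)
    if (is.null(fam)) next
    tb <- as.data.frame(fam)
    tb$metric <- m
    msel[[m]] <- tb
    best[[m]] <- attr(fam, "fits")[[1L]]
  }
  if (length(msel)) {
    mtab <- do.call(rbind, msel)
    rownames(mtab) <- NULL
    utils::write.csv(mtab, file.path(rc$output_dir, "model_selection.csv"),
                     row.names = FALSE)
    btab <- do.call(rbind, lapply(names(best), function(m) {
      co <- best[[m]]$coefficients
      data.frame(metric = m,
                 effects = if (length(best[[m]]$effects))
                   paste(best[[m]]$effects, collapse = "+") else "(none)",
                 term = names(co), estimate = as.numeric(co))
    }))
    utils::write.csv(btab, file.path(rc$output_dir, "best_models.csv"),
                     row.names = FALSE)
  }

  # per-metric group plot with left-right lines per individual
  grDevices::png(file.path(rc$output_dir, "metrics_by_group.png"),
                 width = 1400, height = 900, res = 120)
  op <- graphics::par(mfrow = c(2, 3), mar = c(6, 4, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  df$group <- interaction(df$species, df$sex, df$side, drop = TRUE)
  for (m in metrics) {
    graphics::boxplot(df[[m]] ~ df$group, main = m, xlab = "", ylab = m,
                      las = 2, outline = FALSE,
                      ylim = range(df[[m]], na.rm = TRUE))
    pos <- as.integer(df$group)
    graphics::points(pos, df[[m]], pch = 16, cex = 0.6)
    for (ind in unique(df$individual_id)) {
      sub <- df[df$individual_id == ind, ]
      if (nrow(sub) == 2L)
        graphics::lines(as.integer(sub$group), sub[[m]], col = "grey50")
    }
  }
  invisible(list(descriptives = desc, side_tests = side_tests,
                 sex_tests = sex_tests, correlations = cors,
                 model_selection = if (length(msel)) do.call(rbind, msel) else NULL,
                 best_models = best))
}
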
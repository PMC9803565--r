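#' Configuration for an end-to-end pipeline run
#'
#' Collects every stage's knobs in one serialisable object. A run is a pure
#' function of its configuration (all randomness flows from `seed`), so a
#' config plus seed reproduces a run exactly.
#'
#' @param input Path to an input PNG/TIFF, or `NULL` to generate a phantom.
#' @param truth Optional path to a 0/255 ground-truth mask PNG.
#' @param out_dir Output directory for intermediates and the report.
#' @param height,width,tissue_means,tumour_radius,noise_sigma,block_quality
#'   Phantom parameters (used when `input` is `NULL`); see [phantom_spec()].
#' @param denoise Run the denoising stage (`TRUE`) or skip it (recorded in
#'   the report).
#' @param levels,sigma_d,sigma_r_scale,window,threshold_rule,block Denoiser
#'   knobs, see [denoise_image()].
#' @param clusters,fuzzifier,pop,max_gen,refine_every,inner_iters Clustering
#'   knobs, see [gcpso_fcm()] and [segment_image()].
#' @param glcm_levels Quantisation depths for the texture stage.
#' @param seed Master seed.
#' @param cache Reuse a previous report if the configuration hash matches.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(input = NULL, truth = NULL, out_dir = tempfile("btseg_"),
                       height = 96L, width = 96L,
                       tissue_means = c(20, 120, 230), tumour_radius = 10,
                       noise_sigma = 10, block_quality = NA,
                       denoise = TRUE, levels = 2L, sigma_d = 1.8,
                       sigma_r_scale = 1.0, window = 11L,
                       threshold_rule = "hard", block = 8L,
                       clusters = 3L, fuzzifier = 2, pop = 20L,
                       max_gen = 100L, refine_every = 1L, inner_iters = 2L,
                       glcm_levels = c(128L, 256L),
                       seed = 1L, cache = FALSE) {
  cfg <- list(input = input, truth = truth, out_dir = out_dir,
              height = as.integer(height), width = as.integer(width),
              tissue_means = as.numeric(tissue_means),
              tumour_radius = as.numeric(tumour_radius),
              noise_sigma = as.numeric(noise_sigma),
              block_quality = if (is.na(block_quality)) NA_integer_ else as.integer(block_quality),
              denoise = isTRUE(denoise), levels = as.integer(levels),
              sigma_d = as.numeric(sigma_d),
              sigma_r_scale = as.numeric(sigma_r_scale),
              window = as.integer(window), threshold_rule = threshold_rule,
              block = as.integer(block), clusters = as.integer(clusters),
              fuzzifier = as.numeric(fuzzifier), pop = as.integer(pop),
              max_gen = as.integer(max_gen),
              refine_every = as.integer(refine_every),
              inner_iters = as.integer(inner_iters),
              glcm_levels = as.integer(glcm_levels),
              seed = as.integer(seed), cache = isTRUE(cache))
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("Pipeline configuration:\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-14s %s\n", k,
                if (is.null(v)) "NULL" else paste(v, collapse = " ")))
  }
  invisible(x)
}

#' Read / write a run configuration as a plain key-value file
#'
#' One `key = value` pair per line; vectors are space-separated.
#'
#' @param cfg A [run_config()].
#' @param path File path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a `"run_config"`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  lines <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    sprintf("%s = %s", k,
            if (is.null(v)) "NULL" else paste(format(v, digits = 15), collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- list()
  for (p in kv) {
    k <- trimws(p[1])
    v <- trimws(paste(p[-1], collapse = "="))
    vals[[k]] <- if (identical(v, "NULL")) NULL else v
  }
  proto <- run_config()
  args <- list()
  for (k in names(vals)) {
    if (!k %in% names(proto) || k %in% c("cache")) {
      if (k == "cache") { args[[k]] <- as.logical(vals[[k]]); next }
      next
    }
    tmpl <- proto[[k]]
    parts <- strsplit(vals[[k]], "[[:space:]]+")[[1]]
    args[[k]] <- if (is.character(tmpl) || is.null(tmpl)) vals[[k]]
                 else if (is.logical(tmpl)) as.logical(parts)
                 else suppressWarnings(as.numeric(parts))  # "NA" stays NA
  }
  # NULL-valued keys simply stay at their defaults
  do.call(run_config, args)
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  hashable <- cfg
  hashable$out_dir <- NULL    # the output location must not change the hash
  hashable$cache <- NULL
  writeLines(vapply(names(hashable), function(k)
    paste(k, paste(format(hashable[[k]], digits = 15), collapse = " ")),
    character(1)), f)
  unname(tools::md5sum(f))
}

#' Run the full tumour-identification pipeline
#'
#' Executes, in order: input acquisition (file or phantom, with noise and
#' optional blocking artifacts), adaptive bilateral multiresolution
#' denoising, hybrid GCPSO-FCM segmentation, tumour-mask extraction, GLCM
#' texture features, and evaluation (image-quality metrics against the clean
#' reference and confusion rates against ground truth, when available).
#' Every intermediate image is written to `cfg$out_dir` along with
#' `features.csv` and a machine-readable `report.json`; stage timings are
#' logged to `stages.log` (kept out of the report so that identical
#' config + seed yields a byte-identical report). When `cfg$cache` is set
#' and a report with the same configuration hash already exists, it is
#' reloaded instead of recomputed.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress per-stage messages.
#' @return The report, invisibly: a list with `config_hash`, `stages`
#'   (stages run or skipped), `segmentation` (per-image confusion rates,
#'   label accuracy, Dice), `denoising` (MSE/PSNR), and `features`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  report_path <- file.path(cfg$out_dir, "report.json")
  if (cfg$cache && file.exists(report_path)) {
    prev <- jsonlite::read_json(report_path, simplifyVector = TRUE)
    if (identical(prev$config_hash, hash)) {
      if (!quiet) message("cache hit (", hash, "); reusing report")
      return(invisible(prev))
    }
  }

  log_path <- file.path(cfg$out_dir, "stages.log")
  cat("", file = log_path)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    dt <- proc.time()[["elapsed"]] - t0
    line <- sprintf("stage=%s seed=%d elapsed=%.3fs", name, cfg$seed, dt)
    cat(line, "\n", file = log_path, append = TRUE)
    if (!quiet) message(line)
    out
  }

  truth_mask <- NULL
  truth_labels <- NULL
  clean <- NULL
  inp <- stage("input", {
    if (!is.null(cfg$input)) {
      img <- read_gray(cfg$input)
      if (!is.null(cfg$truth)) truth_mask <- read_mask(cfg$truth)
      img
    } else {
      spec <- phantom_spec(cfg$height, cfg$width, cfg$tissue_means,
                           cfg$tumour_radius, cfg$noise_sigma,
                           if (is.na(cfg$block_quality)) NULL else cfg$block_quality,
                           seed = cfg$seed)
      ph <- make_phantom(spec)
      clean <- ph$image
      truth_mask <- ph$mask
      truth_labels <- ph$labels
      img <- ph$image
      if (!is.na(cfg$block_quality))
        img <- add_blockiness(img, cfg$block, cfg$block_quality)
      if (cfg$noise_sigma > 0)
        img <- add_noise(img, cfg$noise_sigma, seed = cfg$seed + 1L)
      write_gray(clean, file.path(cfg$out_dir, "clean.png"))
      write_mask(truth_mask, file.path(cfg$out_dir, "truth_mask.png"))
      img
    }
  })
  write_gray(inp, file.path(cfg$out_dir, "input.png"))

  den <- if (cfg$denoise) {
    stage("denoise", denoise_image(inp, levels = cfg$levels,
                                   sigma_d = cfg$sigma_d,
                                   sigma_r_scale = cfg$sigma_r_scale,
                                   window = cfg$window,
                                   rule = cfg$threshold_rule,
                                   block = cfg$block))
  } else inp
  write_gray(den, file.path(cfg$out_dir, "denoised.png"))

  seg <- stage("segment", segment_image(den, c = cfg$clusters,
                                        m = cfg$fuzzifier, seed = cfg$seed,
                                        pop = cfg$pop, max_gen = cfg$max_gen,
                                        refine_every = cfg$refine_every,
                                        inner_iters = cfg$inner_iters))
  write_gray(seg$labels * (255 / max(1, cfg$clusters - 1)),
             file.path(cfg$out_dir, "labels.png"))

  mask <- stage("tumour_mask", tumour_mask(seg))
  write_mask(mask, file.path(cfg$out_dir, "tumour_mask.png"))

  feats <- stage("features", glcm_feature_table(den, levels = cfg$glcm_levels))
  utils::write.csv(feats, file.path(cfg$out_dir, "features.csv"),
                   row.names = FALSE)

  evaln <- stage("evaluate", {
    out <- list(stages = c("input",
                           if (cfg$denoise) "denoise" else "denoise_skipped",
                           "segment", "tumour_mask", "features", "evaluate"))
    if (!is.null(clean)) {
      out$denoising <- list(
        mse_input = round(mse(inp, clean), 6),
        mse_denoised = round(mse(den, clean), 6),
        psnr_input = round(psnr(inp, clean), 6),
        psnr_denoised = round(psnr(den, clean), 6))
    }
    if (!is.null(truth_mask)) {
      cr <- confusion_rates(mask, truth_mask)
      out$segmentation <- list(
        TPR = round(cr$TPR, 3), TNR = round(cr$TNR, 3),
        FPR = round(cr$FPR, 3), FNR = round(cr$FNR, 3),
        accuracy = round(cr$accuracy, 3),
        dice = round(dice(mask, truth_mask), 6))
      if (!is.null(truth_labels))
        out$segmentation$label_accuracy <-
          round(mean(seg$labels == truth_labels), 6)
    }
    out
  })

  report <- c(list(config_hash = hash, seed = cfg$seed), evaln,
              list(features = feats))
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}
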
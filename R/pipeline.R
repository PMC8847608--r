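#' Read a pipeline configuration file
#'
#' Plain `key: value` text (Debian-control syntax, one field per line) with
#' dotted per-stage keys, e.g. `preprocess.crop_side: 128`. Values are
#' parsed as numbers where possible. Unknown keys raise an error; missing
#' keys fall back to the reference defaults (`w` 40, filter thresholds
#' 4/6/4, epoch plan 1000/200/400, batch 8, dropout 0.5/0.2, learning
#' rates 3e-5/1e-4).
#'
#' @param path config file path; `NULL` for pure defaults.
#' @return nested named list of per-stage settings.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  d <- read.dcf(path)
  flat <- stats::setNames(as.list(d[1, ]), colnames(d))
  for (key in names(flat)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L || is.null(cfg[[parts[1]]]) ||
        !parts[2] %in% names(cfg[[parts[1]]]))
      stop("unknown config key: '", key, "'")
    old <- cfg[[parts[1]]][[parts[2]]]
    val <- flat[[key]]
    num <- suppressWarnings(as.numeric(val))
    cfg[[parts[1]]][[parts[2]]] <- if (!is.na(num)) num else val
  }
  validate_config(cfg)
}

default_config <- function() {
  list(preprocess = preprocess_config(),
       model = list(arch = "cnn3d", w = 40, input_side = 128,
                    seed = 1, epochs = 3000,
                    learning_rate = NA, dropout = NA),
       plan = epoch_plan(),
       filter = filter_params(),
       scene = list(arena_side = 256, n_bouts = 4, frames = 600))
}

validate_config <- function(cfg) {
  cfg$filter <- filter_params(cfg$filter$sporadic_max,
                              cfg$filter$interruption_max,
                              cfg$filter$transition_max)
  cfg$plan <- epoch_plan(cfg$plan$n_not, cfg$plan$n_face, cfg$plan$n_body,
                         cfg$plan$batch_size)
  cfg$preprocess <- preprocess_config(cfg$preprocess$crop_side,
                                      cfg$preprocess$binarize_threshold,
                                      cfg$preprocess$centroid_threshold,
                                      cfg$preprocess$foreground_polarity,
                                      cfg$preprocess$out_side)
  cfg
}

write_manifest <- function(path, stage, inputs = character(0), seed = NULL,
                           config = NULL, t0 = NULL) {
  man <- list(stage = stage,
              version = as.character(utils::packageVersion("ethogroom")),
              seed = seed,
              config = config,
              inputs = as.list(stats::setNames(
                unname(tools::md5sum(inputs[file.exists(inputs)])),
                inputs[file.exists(inputs)])),
              elapsed_s = if (!is.null(t0))
                as.numeric(Sys.time() - t0, units = "secs"),
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Run one pipeline stage
#'
#' Commands: `simulate` (synthetic video to a PGM frame directory plus truth
#' CSV), `preprocess` (frame directory to differential stack), `train`,
#' `predict`, `filter` (raw to filtered prediction CSV) and `evaluate`
#' (truth vs prediction report). Every artifact is written together with a
#' JSON manifest (config snapshot, input hashes, seed, version, timing).
#'
#' @param command stage name.
#' @param config a config list from [read_config()] (or `NULL` for
#'   defaults).
#' @param args named list of stage arguments (see details of each stage
#'   function).
#' @return stage-dependent artifact description (invisibly where the
#'   artifact is a file).
#' @export
run_pipeline <- function(command = c("simulate", "preprocess", "train",
                                     "predict", "filter", "evaluate"),
                         config = NULL, args = list()) {
  command <- match.arg(command)
  cfg <- if (is.null(config)) read_config(NULL) else validate_config(config)
  t0 <- Sys.time()
  need <- function(name) {
    if (is.null(args[[name]]))
      stop("stage '", command, "' requires argument '", name, "'")
    args[[name]]
  }
  switch(command,
    simulate = {
      out <- need("out_dir")
      seed <- as.integer(args$seed %||% cfg$model$seed)
      set.seed(seed)
      script <- args$script %||%
        random_script(args$n_bouts %||% cfg$scene$n_bouts)
      scene <- args$scene %||% scene_config(cfg$scene$arena_side)
      vid <- render_video(script, scene)
      dir.create(file.path(out, "frames"), recursive = TRUE,
                 showWarnings = FALSE)
      for (i in seq_along(vid$frames))
        write_pgm(vid$frames[[i]],
                  file.path(out, "frames", sprintf("frame_%05d.pgm", i - 1L)))
      write_label_csv(vid$truth, file.path(out, "truth.csv"))
      jsonlite::write_json(list(script = as.list(script), scene = scene),
                           file.path(out, "scene.json"), auto_unbox = TRUE,
                           null = "null")
      write_manifest(file.path(out, "manifest.json"), "simulate",
                     seed = seed, config = cfg$scene, t0 = t0)
      invisible(out)
    },
    preprocess = {
      video <- need("video")
      out <- need("out")
      frames <- extract_frames(video)
      stack <- preprocess_video(frames, cfg$preprocess)
      write_diff_stack(stack, out)
      write_manifest(paste0(out, ".manifest.json"), "preprocess",
                     inputs = if (is.character(video))
                       list.files(video, full.names = TRUE) else character(0),
                     config = cfg$preprocess, t0 = t0)
      invisible(out)
    },
    train = {
      stacks <- need("stacks")   # list of diff-stack RDS paths
      labels <- need("labels")   # list of raw-video label CSV paths
      out <- need("out")
      mc <- args$model_config %||% model_config(
        cfg$model$arch, w = cfg$model$w, input_side = cfg$model$input_side,
        seed = cfg$model$seed)
      grouped <- mapply(function(sp, lp) {
        make_grouped(read_diff_stack(sp), stack_labels(read_label_csv(lp)),
                     mc$w)
      }, stacks, labels, SIMPLIFY = FALSE)
      model <- if (mc$arch == "cnn3d") build_cnn3d(mc) else build_crnn(mc)
      model <- train(model, grouped_pool(grouped), cfg$plan,
                     epochs = as.integer(args$epochs %||% cfg$model$epochs))
      write_checkpoint(model, out)
      utils::write.csv(data.frame(epoch = seq_along(model$loss_history),
                                  loss = model$loss_history),
                       paste0(out, ".trainlog.csv"), row.names = FALSE,
                       quote = FALSE)
      write_manifest(paste0(out, ".manifest.json"), "train",
                     inputs = c(unlist(stacks), unlist(labels)),
                     seed = mc$seed, config = mc, t0 = t0)
      invisible(out)
    },
    predict = {
      model <- read_checkpoint(need("checkpoint"))
      stack <- read_diff_stack(need("stack"))
      out <- need("out")
      T_ <- dim(stack)[3]
      g <- make_grouped(stack, rep(0L, T_), model$config$w)
      probs <- predict_probs(model, g)
      write_prediction_csv(probs, out)
      write_manifest(paste0(out, ".manifest.json"), "predict",
                     inputs = c(args$checkpoint, args$stack), t0 = t0)
      invisible(out)
    },
    filter = {
      pred <- read_prediction_csv(need("pred"))
      out <- need("out")
      filt <- apply_filters(label_track(pmax(pred$label_raw, 0L)),
                            cfg$filter)
      utils::write.csv(data.frame(frame = pred$frame,
                                  label_filtered = as.integer(filt)),
                       out, row.names = FALSE, quote = FALSE)
      write_manifest(paste0(out, ".manifest.json"), "filter",
                     inputs = args$pred, config = cfg$filter, t0 = t0)
      invisible(out)
    },
    evaluate = {
      truth <- read_label_csv(need("truth"))
      pv <- utils::read.csv(need("pred"))
      lab <- pv$label_filtered %||% pv$label_raw %||% pv$label
      if (is.null(lab)) stop("prediction CSV has no label column")
      rep <- evaluation_report(truth, label_track(lab))
      if (!is.null(args$out)) {
        jsonlite::write_json(
          list(confusion = unclass(rep$confusion),
               sensitivity = as.list(rep$sensitivity),
               ppr = as.list(rep$ppr), accuracy = rep$accuracy,
               macro_f1 = rep$macro_f1,
               bouts_truth = as.list(rep$bouts_truth),
               bouts_pred = as.list(rep$bouts_pred),
               errors = rep$errors),
          args$out, auto_unbox = TRUE, pretty = TRUE, null = "null")
        write_manifest(paste0(args$out, ".manifest.json"), "evaluate",
                       inputs = c(args$truth, args$pred), t0 = t0)
      }
      rep
    })
}
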
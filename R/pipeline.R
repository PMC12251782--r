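# Experiment configuration and the staged pipeline behind the command-line
# interface (inst/scripts/enose).

#' Default experiment configuration
#'
#' Nested list with one section per stage (simulate / preprocess / features /
#' select / model / train / evaluate) plus a global seed and output
#' directory. Every field has a default; unknown keys in an override file
#' are rejected.
#'
#' @return named list of class `enose_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    out_dir = "enose_out",
    simulate = list(mode = "continuous", cycles = 10L, conditions = 60L,
                    drift = TRUE, hold_min = 60, hold_max = 300,
                    clean = 1200, mixture = TRUE),
    preprocess = list(lag_s = 0L, kalman_q = 3, kalman_r = 1,
                      sg_window = 11L, sg_order = 3L,
                      window = 180L, stride = 30L, labeling = "last"),
    features = list(fs = 1),
    select = list(k = 16L, rf_trees = 100L,
                  methods = c("pearson", "mic", "rf", "svmrfe")),
    model = list(name = "IED-CNN-LSTM", conv = c(32L, 64L, 64L),
                 kernel = 3L, rnn_hidden = 64L, dct_k = 16L,
                 attn_reduction = 4L, decomp_kernel = 25L,
                 trans_heads = 4L, comp_dim = 16L, fc = 64L),
    train = list(lr = 2e-3, batch = 32L, epochs = 100L),
    evaluate = list(ratio = 0.8, chronological = FALSE)
  ), class = "enose_config")
}

#' Read an experiment configuration from YAML or JSON
#'
#' Values override the defaults of [default_config()]; unknown sections or
#' keys are an error.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return `enose_config` list.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  merge_config(default_config(), raw)
}

#' @rdname read_config
#' @param base base configuration (defaults).
#' @param override named list of overrides.
#' @export
merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  bad <- setdiff(names(override), names(base))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      sub_bad <- setdiff(names(override[[nm]]), names(base[[nm]]))
      if (length(sub_bad)) {
        stop("unknown config key(s) in ", nm, ": ",
             paste(sub_bad, collapse = ", "))
      }
      base[[nm]] <- utils::modifyList(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Write a configuration to YAML
#' @param config an `enose_config`.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# per-stage seeds derived from one global seed, so stages can be rerun in
# isolation; kept below 2^31
derive_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, preprocess = 211L, features = 307L,
            select = 401L, train = 503L, evaluate = 601L)
  o <- offs[[stage]] %||% 997L
  as.integer((as.numeric(seed) * 7919 + o) %% 2147483587)
}

.log_line <- function(log, msg) {
  line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", msg)
  if (!is.null(log)) cat(line, "\n", file = log, append = TRUE)
  message(line)
}

#' Run a pipeline stage
#'
#' Commands: `"simulate"` writes a recording CSV; `"preprocess"` filters a
#' recording; `"features"` extracts the feature table; `"select"` ranks
#' features and channels; `"train"` fits one deep model; `"evaluate"`
#' scores it; `"benchmark"` chains all stages over a model roster. Every
#' artifact directory receives the resolved configuration (`config.yaml`)
#' and a plain-text log.
#'
#' @param command stage name.
#' @param config an `enose_config` (see [default_config()]).
#' @param models model roster for `benchmark`.
#' @param seeds training seeds for `benchmark`.
#' @return invisibly, the main artifact produced by the stage.
#' @export
run_pipeline <- function(command = c("simulate", "preprocess", "features",
                                     "select", "train", "evaluate",
                                     "benchmark"),
                         config = default_config(),
                         models = c("ED-CNN-LSTM", "ED-CNN-DCT-LSTM",
                                    "IED-CNN-LSTM"),
                         seeds = 1L) {
  command <- match.arg(command)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, file.path(config$out_dir, "config.yaml"))
  log <- file.path(config$out_dir, "pipeline.log")
  .log_line(log, paste("stage:", command, "seed:", config$seed))

  sim <- function() {
    s <- config$simulate
    prof <- if (s$mode == "intermittent") {
      gen_intermittent(s$cycles, seed = derive_seed(config$seed, "simulate"),
                       mixture = s$mixture)
    } else {
      gen_continuous(s$conditions, seed = derive_seed(config$seed, "simulate"),
                     opts = list(hold = c(s$hold_min, s$hold_max),
                                 clean = s$clean))
    }
    simulate_response(prof, default_array(),
                      seed = derive_seed(config$seed, "simulate") + 1L,
                      drift = s$drift)
  }
  prep <- function(rec) {
    p <- config$preprocess
    preprocess_recording(rec, filter_config(p$lag_s, p$kalman_q, p$kalman_r,
                                            p$sg_window, p$sg_order))
  }
  wins <- function(rec) {
    p <- config$preprocess
    windowize(rec, length = p$window, stride = p$stride,
              labeling = p$labeling)
  }

  out <- switch(command,
    simulate = {
      rec <- sim()
      path <- file.path(config$out_dir, "recording.csv")
      write_recording(rec, path)
      .log_line(log, paste("wrote", path, "-", nrow(rec$channels), "rows"))
      rec
    },
    preprocess = {
      rec <- prep(sim())
      path <- file.path(config$out_dir, "recording_filtered.csv")
      write_recording(rec, path)
      .log_line(log, paste("wrote", path))
      rec
    },
    features = {
      ft <- extract_features(wins(prep(sim())), fs = config$features$fs)
      path <- file.path(config$out_dir, "features.csv")
      write_features(ft, path)
      .log_line(log, paste("wrote", path, "-", nrow(ft), "samples"))
      ft
    },
    select = {
      ft <- extract_features(wins(prep(sim())), fs = config$features$fs)
      rk <- rank_ensemble(ft, methods = config$select$methods,
                          seed = derive_seed(config$seed, "select"),
                          rf_trees = config$select$rf_trees)
      sel <- select_channels(rk$sensor, k = config$select$k)
      write_ranks(rk, file.path(config$out_dir, "ranks.csv"))
      jsonlite::write_json(list(channels = sel),
                           file.path(config$out_dir, "channels.json"))
      .log_line(log, paste("selected:", paste(sel, collapse = " ")))
      sel
    },
    train = ,
    evaluate = {
      w <- wins(prep(sim()))
      sp <- split_dataset(w, ratio = config$evaluate$ratio,
                          seed = derive_seed(config$seed, "evaluate"),
                          chronological = config$evaluate$chronological)
      fit <- fit_enose(sp$train, model = config$model$name,
                       conv = config$model$conv, kernel = config$model$kernel,
                       rnn_hidden = config$model$rnn_hidden,
                       dct_k = config$model$dct_k,
                       attn_reduction = config$model$attn_reduction,
                       decomp_kernel = config$model$decomp_kernel,
                       trans_heads = config$model$trans_heads,
                       comp_dim = config$model$comp_dim, fc = config$model$fc,
                       lr = config$train$lr, batch = config$train$batch,
                       epochs = config$train$epochs,
                       seed = derive_seed(config$seed, "train"))
      utils::write.csv(data.frame(epoch = seq_along(fit$history),
                                  mse = fit$history),
                       file.path(config$out_dir, "loss.csv"),
                       row.names = FALSE)
      if (command == "train") {
        .log_line(log, "model trained")
        fit
      } else {
        m <- compute_metrics(windows_to_arrays(sp$test)$y,
                             predict(fit, sp$test))
        .log_line(log, sprintf("test RMSE %.3f R2 %.3f CORR %.3f",
                               m$pooled["rmse"], m$pooled["r2"],
                               m$pooled["corr"]))
        m
      }
    },
    benchmark = {
      w <- wins(prep(sim()))
      sp <- split_dataset(w, ratio = config$evaluate$ratio,
                          seed = derive_seed(config$seed, "evaluate"),
                          chronological = config$evaluate$chronological)
      tab <- run_benchmark(models, list(train = sp$train, test = sp$test),
                           seeds = seeds,
                           conv = config$model$conv,
                           rnn_hidden = config$model$rnn_hidden,
                           dct_k = config$model$dct_k,
                           decomp_kernel = config$model$decomp_kernel,
                           comp_dim = config$model$comp_dim,
                           fc = config$model$fc,
                           lr = config$train$lr, batch = config$train$batch,
                           epochs = config$train$epochs)
      path <- file.path(config$out_dir, "benchmark.csv")
      utils::write.csv(tab, path, row.names = FALSE)
      .log_line(log, paste("wrote", path))
      tab
    }
  )
  invisible(out)
}
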
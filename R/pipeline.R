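# End-to-end workflow: simulate -> split -> train -> validate -> analyze.

default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "rmm-run",
    simulate = list(duration_ms = 20000, delta = 0.1,
                    ou = list(list(mu = 0.03, a = 0.04, b = 0.1),
                              list(mu = 0.22, a = 0.04, b = 0.1)),
                    burn_in_ms = 5000),
    split = list(train_frac = 0.75),
    model = list(intrinsic_taus = NULL, intrinsic_hidden = c(8L, 8L),
                 synapse = "mlp", synapse_taus = NULL,
                 synapse_hidden = c(8L, 8L), c0 = 1),
    train = list(method = "tf", epochs = 20L, n_minibatches = 48L,
                 shot_len = 30L, gamma = 0, snapshot_every = 5L),
    analyze = list(v_step = 1, n_omega = 40L)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]]))
      merge_config(base[[nm]], override[[nm]]) else override[[nm]]
  }
  base
}

#' Read a pipeline configuration
#'
#' YAML file overriding the documented defaults; unknown top-level keys are
#' rejected.
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return nested configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    ov <- yaml::read_yaml(path)
    unknown <- setdiff(names(ov), names(cfg))
    if (length(unknown))
      stop_invalid("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg <- merge_config(cfg, ov)
  }
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(cfg, f, digits = I(17), auto_unbox = TRUE, force = TRUE)
  unname(tools::md5sum(f))
}

stage_msg <- function(quiet, ...) if (!quiet) message(...)

#' Run the full modeling pipeline
#'
#' Generates (or loads) a half-center recording, splits it, initializes and
#' trains an RMM, validates it with the spike-train metric, and computes the
#' per-neuron admittance surfaces and bifurcation candidates.  Every
#' artifact is written under `cfg$out_dir` and stamped with the config hash
#' and seed; a rerun with the same configuration reproduces the results.
#'
#' @param cfg configuration list from [read_run_config()].
#' @param recording optional pre-generated `rmm_recording` (skips the
#'   simulation stage).
#' @param quiet suppress stage messages.
#' @return list with `recording`, `split`, `fit`, `validation`, `surfaces`,
#'   `candidates`, `hash`, and artifact `paths`.
#' @export
run_pipeline <- function(cfg = read_run_config(), recording = NULL,
                         quiet = TRUE) {
  hash <- config_hash(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(recording = file.path(cfg$out_dir, "recording.tsv"),
                model = file.path(cfg$out_dir, "model.json"),
                trace = file.path(cfg$out_dir, "train_log.tsv"),
                report = file.path(cfg$out_dir, "validation.tsv"),
                surface = file.path(cfg$out_dir, "admittance.tsv"),
                candidates = file.path(cfg$out_dir, "bifurcations.tsv"))

  run_stage <- function(name, expr) {
    t0 <- proc.time()[3L]
    out <- tryCatch(expr, error = function(e)
      stop_invalid("pipeline stage `", name, "` failed: ", conditionMessage(e)))
    stage_msg(quiet, sprintf("[%s] done in %.1f s", name,
                             proc.time()[3L] - t0))
    out
  }

  sim <- cfg$simulate
  rec <- run_stage("simulate", {
    if (!is.null(recording)) recording
    else simulate_hco_dataset(
      duration_ms = sim$duration_ms, delta = sim$delta,
      ou = lapply(sim$ou, function(o)
        ou_params(mu = o$mu, a = o$a, b = o$b, delta = sim$delta)),
      seed = cfg$seed, burn_in_ms = sim$burn_in_ms)
  })
  rec$meta$config_hash <- hash
  write_recording(rec, paths$recording)

  sp <- run_stage("split", make_train_val_split(rec, cfg$split$train_frac))

  mc <- cfg$model
  tauf <- mc$intrinsic_taus %||% 10^seq(log10(0.5), log10(1000), length.out = 8L)
  taus_syn <- mc$synapse_taus %||% 10^seq(log10(0.5), log10(200), length.out = 8L)
  spec <- rmm_spec(
    n_neurons = 2L, delta = rec$delta,
    intrinsic = list(taus = tauf, hidden = mc$intrinsic_hidden),
    synapse = if (identical(mc$synapse, "cond"))
      list(type = "cond", taus = taus_syn, E_syn = -80, g0 = 0.1)
    else list(type = "mlp", taus = taus_syn, hidden = mc$synapse_hidden),
    c0 = mc$c0)
  model0 <- init_parameters(spec, sp$train$v, seed = cfg$seed)

  tr <- cfg$train
  tconf <- train_config(method = tr$method, epochs = tr$epochs,
                        n_minibatches = tr$n_minibatches,
                        shot_len = tr$shot_len, gamma = tr$gamma %||% 0,
                        snapshot_every = tr$snapshot_every,
                        seed = cfg$seed)
  fit <- run_stage("train",
                   fit_rmm(model0, sp$train, tconf, validation = sp$validation))
  write_model(fit$model, paths$model)
  data.table::fwrite(fit$trace, paths$trace, sep = "\t")

  val <- run_stage("validate", validate_model(fit$model, sp$validation))
  data.table::fwrite(data.frame(neuron = seq_along(val$per_neuron),
                                metric = val$per_neuron), paths$report,
                     sep = "\t")

  an <- run_stage("analyze", {
    lapply(seq_along(fit$model$neurons), function(i) {
      mem <- neuron_membrane(fit$model, i)
      vg <- seq(mem$v_range[1L], mem$v_range[2L], by = cfg$analyze$v_step)
      og <- c(0, 10^seq(-4, log10(pi / mem$delta),
                        length.out = cfg$analyze$n_omega))
      surf <- admittance_surface(mem, vg, og)
      cand <- bifurcation_candidates(mem, vg)
      list(surface = surf, candidates = cand)
    })
  })
  surf_tab <- do.call(rbind, lapply(seq_along(an), function(i) {
    s <- an[[i]]$surface
    data.frame(neuron = i,
               v = rep(s$v, times = length(s$omega)),
               omega = rep(s$omega, each = length(s$v)),
               ReY = as.numeric(s$G), ImY = as.numeric(s$B))
  }))
  data.table::fwrite(surf_tab, paths$surface, sep = "\t")
  cand_tab <- do.call(rbind, lapply(seq_along(an), function(i) {
    cd <- an[[i]]$candidates
    if (nrow(cd)) cbind(neuron = i, cd) else NULL
  }))
  if (is.null(cand_tab))
    cand_tab <- data.frame(neuron = integer(0), v_bar = numeric(0),
                           omega_bar = numeric(0), type = character(0),
                           residual = numeric(0))
  data.table::fwrite(cand_tab, paths$candidates, sep = "\t")

  list(recording = rec, split = sp, fit = fit, validation = val,
       surfaces = lapply(an, `[[`, "surface"),
       candidates = cand_tab, hash = hash, paths = paths)
}
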
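# Adam-based training loop shared by the three methods.

#' Training configuration
#'
#' Defaults mirror the training setup used throughout the package:
#' Adam with betas (0.9, 0.999); teacher forcing with step size 0.001 and
#' `rho = 5e-8`; multiple shooting / GTF with step size 0.01 (dropping to
#' 0.005 at epoch 50 and 0.0025 at epoch 100 for MS), `rho = 5e-9`,
#' continuity weights `rho_v = rho_x = 500`; 48 mini-batches; model
#' snapshots every 5 epochs.  All overridable.
#'
#' @param method `"tf"` (feed-forward teacher forcing), `"ms"` (multiple
#'   shooting) or `"gtf_ms"` (GTF combined with shooting).
#' @param epochs number of training epochs (0 returns the initial model).
#' @param rho ANN-parameter ridge weight (method-dependent default).
#' @param rho_v,rho_x shot-continuity weights (MS/GTF only).
#' @param gamma GTF measurement-correction factor in \[0, 1\).
#' @param shot_len shot length in samples (MS/GTF only).
#' @param n_minibatches mini-batches per epoch.
#' @param shuffle TF sample shuffling (MS/GTF always permute shots across
#'   batches between epochs).
#' @param lr_schedule list of `c(epoch, step_size)` pairs; each step size
#'   applies from its epoch onward.
#' @param adam_betas Adam moment decay parameters.
#' @param snapshot_every validation snapshot period, epochs.
#' @param seed integer seed controlling initial states of mini-batching.
#' @param burn_in warm-up burn-in samples or `"auto"`.
#' @param pin_upsilon fix shot initial voltages to the data (diagnostic).
#' @param max_grad exploding-gradient guard: abort when the loss or the
#'   gradient norm exceeds this.
#' @return a list of class `rmm_train_config`.
#' @export
train_config <- function(method = c("tf", "ms", "gtf_ms"), epochs = 100L,
                         rho = NULL, rho_v = 500, rho_x = 500, gamma = 0,
                         shot_len = 30L, n_minibatches = 48L,
                         shuffle = TRUE, lr_schedule = NULL,
                         adam_betas = c(0.9, 0.999), snapshot_every = 5L,
                         seed = 1L, burn_in = "auto", pin_upsilon = FALSE,
                         max_grad = 1e12) {
  method <- match.arg(method)
  if (is.null(rho)) rho <- if (method == "tf") 5e-8 else 5e-9
  if (is.null(lr_schedule)) {
    lr_schedule <- switch(method,
      tf = list(c(1, 0.001)),
      ms = list(c(1, 0.01), c(50, 0.005), c(100, 0.0025)),
      gtf_ms = list(c(1, 0.01)))
  }
  if (method == "gtf_ms" && (gamma < 0 || gamma >= 1))
    stop_invalid("GTF requires gamma in [0, 1)")
  structure(list(method = method, epochs = as.integer(epochs), rho = rho,
                 rho_v = rho_v, rho_x = rho_x, gamma = gamma,
                 shot_len = as.integer(shot_len),
                 n_minibatches = as.integer(n_minibatches),
                 shuffle = isTRUE(shuffle), lr_schedule = lr_schedule,
                 adam_betas = adam_betas,
                 snapshot_every = as.integer(snapshot_every),
                 seed = as.integer(seed), burn_in = burn_in,
                 pin_upsilon = isTRUE(pin_upsilon), max_grad = max_grad),
            class = "rmm_train_config")
}

lr_at <- function(schedule, epoch) {
  lr <- schedule[[1L]][2L]
  for (e in schedule) if (epoch >= e[1L]) lr <- e[2L]
  lr
}

adam_state <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(st, grad, lr, betas) {
  st$t <- st$t + 1L
  st$m <- betas[1L] * st$m + (1 - betas[1L]) * grad
  st$v <- betas[2L] * st$v + (1 - betas[2L]) * grad^2
  mhat <- st$m / (1 - betas[1L]^st$t)
  vhat <- st$v / (1 - betas[2L]^st$t)
  st$delta <- lr * mhat / (sqrt(vhat) + 1e-8)
  st
}

as_vu <- function(data) {
  if (inherits(data, "rmm_recording")) list(v = data$v, u = data$u)
  else list(v = as.matrix(data$v), u = as.matrix(data$u))
}

# normalize training data to a list of (v, u) trial segments
as_segments <- function(data) {
  if (inherits(data, "rmm_recording") || !is.null(data$v))
    return(list(as_vu(data)))
  lapply(data, as_vu)
}

plan_to_vec <- function(plan) {
  c(as.numeric(plan$upsilon),
    unlist(lapply(plan$xi_w, as.numeric), use.names = FALSE),
    unlist(lapply(plan$xi_z, as.numeric), use.names = FALSE))
}

vec_to_plan <- function(plan, vec) {
  pos <- 0L
  take <- function(k) { out <- vec[pos + seq_len(k)]; pos <<- pos + k; out }
  plan$upsilon[] <- take(length(plan$upsilon))
  for (i in seq_along(plan$xi_w)) plan$xi_w[[i]][] <- take(length(plan$xi_w[[i]]))
  for (i in seq_along(plan$xi_z)) plan$xi_z[[i]][] <- take(length(plan$xi_z[[i]]))
  stopifnot(pos == length(vec))
  plan
}

#' Train an RMM circuit
#'
#' Runs Adam over mini-batched epochs of the configured loss (teacher
#' forcing, multiple shooting, or GTF-with-shooting).  Every
#' `snapshot_every` epochs the current model is simulated open loop on the
#' validation data (warm-started on a prefix) and scored with the modified
#' angular separation; the returned model is the snapshot with the best
#' validation metric.  Without validation data the final model is returned.
#' Two runs with identical seeds and configuration produce identical traces.
#'
#' @param model an initialized `rmm_circuit`.
#' @param data training data: an `rmm_recording` or a list with voltage
#'   matrix `v` and current matrix `u` (N x n, sampled at the model delta).
#' @param config a [train_config()].
#' @param validation held-out data in the same format (optional).
#' @param metric_cfg a [metric_config()] for the validation metric.
#' @param verbose print per-epoch progress.
#' @return a list of class `rmm_fit` with elements `model` (best snapshot),
#'   `final_model`, `trace` (epoch, loss, validation metric), `plan`
#'   (trained shot states, MS/GTF), and `config`.
#' @export
fit_rmm <- function(model, data, config, validation = NULL,
                    metric_cfg = NULL, verbose = FALSE) {
  segs <- as_segments(data)
  for (sg in segs)
    stopifnot(nrow(sg$v) == nrow(sg$u), ncol(sg$v) == length(model$neurons))
  if (is.null(metric_cfg)) metric_cfg <- metric_config(delta = model$delta)
  # teacher-forced bank states are computed per trial segment (states never
  # mix across segment seams), then stacked alongside the data
  seg_states <- lapply(segs, function(sg)
    precompute_internal_states(model, sg$v, config$burn_in))
  v <- do.call(rbind, lapply(segs, `[[`, "v"))
  u <- do.call(rbind, lapply(segs, `[[`, "u"))
  nseg <- vapply(segs, function(sg) nrow(sg$v), 0L)
  offsets <- cumsum(c(0L, nseg[-length(nseg)]))
  states <- list(
    w = lapply(seq_along(model$neurons), function(i)
      do.call(rbind, lapply(seg_states, function(st) st$w[[i]]))),
    z = lapply(seq_along(model$neurons), function(i)
      do.call(rbind, lapply(seg_states, function(st) st$z[[i]]))),
    burn_in = seg_states[[1L]]$burn_in)
  is_tf <- config$method == "tf"
  gamma <- if (config$method == "gtf_ms") config$gamma else 0

  theta <- pack_params(model)
  n_model <- length(theta)
  if (is_tf) {
    idx_all <- unlist(lapply(seq_along(segs), function(k)
      offsets[k] + (seg_states[[k]]$burn_in + 1L):(nseg[k] - 1L)))
    n_items <- length(idx_all)
    plan <- NULL
    par <- theta
  } else {
    s <- config$shot_len
    starts <- unlist(lapply(seq_along(segs), function(k) {
      first <- seg_states[[k]]$burn_in + 1L
      if (first + s > nseg[k])
        stop_invalid("shot length ", s, " exceeds usable data in segment ", k)
      offsets[k] + seq.int(first, nseg[k] - s, by = s)
    }))
    plan <- shot_plan(model, v, states, s, starts = starts)
    n_items <- plan$n_shots
    par <- c(theta, if (!config$pin_upsilon) as.numeric(plan$upsilon),
             unlist(lapply(plan$xi_w, as.numeric), use.names = FALSE),
             unlist(lapply(plan$xi_z, as.numeric), use.names = FALSE))
  }
  nb <- min(config$n_minibatches, n_items)

  eval_snapshot <- function(mod) {
    if (is.null(validation)) return(NA_real_)
    res <- tryCatch(validate_model(mod, validation, metric_cfg),
                    error = function(e) NULL)
    if (is.null(res)) 0 else res$mean
  }

  trace <- data.frame(epoch = integer(0), loss = numeric(0),
                      val_metric = numeric(0))
  best <- list(model = model, metric = -Inf, epoch = 0L)
  ad <- adam_state(length(par))
  cur_model <- model
  cur_plan <- plan

  for (epoch in seq_len(config$epochs)) {
    lr <- lr_at(config$lr_schedule, epoch)
    batches <- make_minibatches(n_items, nb, shuffle = if (is_tf) config$shuffle else TRUE,
                                seed = config$seed, epoch = epoch,
                                mode = if (is_tf) "tf" else "shots")
    epoch_loss <- 0
    for (b in batches) {
      if (is_tf) {
        res <- tf_loss_grad(cur_model, v, u, states, config$rho, idx_all[b],
                            reg_scale = length(b) / n_items)
        grad <- res$grad
      } else {
        res <- msgtf_loss_grad(cur_model, v, u, cur_plan, sort(b), gamma,
                               config$rho, config$rho_v, config$rho_x,
                               pin_upsilon = config$pin_upsilon,
                               reg_scale = length(b) / n_items)
        grad <- c(res$grad,
                  if (!config$pin_upsilon) as.numeric(res$g_upsilon),
                  unlist(lapply(res$g_xi_w, as.numeric), use.names = FALSE),
                  unlist(lapply(res$g_xi_z, as.numeric), use.names = FALSE))
      }
      gn <- sqrt(sum(grad^2))
      if (!is.finite(res$loss) || !is.finite(gn) ||
          res$loss > config$max_grad || gn > config$max_grad)
        stop_invalid("training aborted at epoch ", epoch,
                     ": non-finite or exploding loss/gradient (loss = ",
                     signif(res$loss, 4), ", |grad| = ", signif(gn, 4),
                     "); reduce the step size or shot length")
      epoch_loss <- epoch_loss + res$loss
      ad <- adam_step(ad, grad, lr, config$adam_betas)
      par <- par - ad$delta
      cur_model <- unpack_params(cur_model, par[seq_len(n_model)])
      if (!is_tf) {
        rest <- par[-seq_len(n_model)]
        if (config$pin_upsilon) {
          tmp <- cur_plan
          pos <- 0L
          for (i in seq_along(tmp$xi_w)) {
            k <- length(tmp$xi_w[[i]]); tmp$xi_w[[i]][] <- rest[pos + seq_len(k)]
            pos <- pos + k
          }
          for (i in seq_along(tmp$xi_z)) {
            k <- length(tmp$xi_z[[i]]); tmp$xi_z[[i]][] <- rest[pos + seq_len(k)]
            pos <- pos + k
          }
          cur_plan <- tmp
        } else cur_plan <- vec_to_plan(cur_plan, rest)
      }
    }
    vm <- NA_real_
    if (epoch %% config$snapshot_every == 0L || epoch == config$epochs) {
      vm <- eval_snapshot(cur_model)
      if (!is.na(vm) && vm > best$metric) {
        best$model <- cur_model
        best$metric <- vm
        best$epoch <- epoch
      }
    }
    trace <- rbind(trace, data.frame(epoch = epoch, loss = epoch_loss,
                                     val_metric = vm))
    if (verbose)
      message(sprintf("epoch %3d  loss %.6g  val %s", epoch, epoch_loss,
                      ifelse(is.na(vm), "-", sprintf("%.4f", vm))))
  }

  out_model <- if (is.null(validation)) cur_model else best$model
  structure(list(model = out_model, final_model = cur_model, trace = trace,
                 plan = cur_plan, config = config,
                 best_epoch = if (is.null(validation)) config$epochs else best$epoch,
                 best_metric = if (is.null(validation)) NA_real_ else best$metric),
            class = "rmm_fit")
}

#' @export
print.rmm_fit <- function(x, ...) {
  cat(sprintf("<rmm_fit> method %s, %d epochs trained", x$config$method,
              nrow(x$trace)))
  if (!is.na(x$best_metric))
    cat(sprintf("; best validation metric %.4f at epoch %d",
                x$best_metric, x$best_epoch))
  cat("\n")
  invisible(x)
}
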
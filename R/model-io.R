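# Lossless model serialization as structured JSON text (17 significant
# digits): architecture, all learnable parameters, normalizers and the
# fixed (A, B) banks round-trip exactly at stored precision.

ss_to_list <- function(ss) {
  if (is.null(ss)) return(NULL)
  # matrices stored flat, column-major
  list(kind = ss$kind, delta = ss$delta, lambdas = ss$lambdas,
       taus = ss$taus, A = as.numeric(ss$A), B = as.numeric(ss$B))
}

ss_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  n <- length(x$lambdas)
  A <- matrix(unlist(x$A), n, n)
  new_ss(A, matrix(unlist(x$B), ncol = 1L), unlist(x$lambdas), x$delta,
         x$kind, taus = unlist(x$taus))
}

mlp_to_list <- function(m) {
  list(W = lapply(m$W, as.numeric), b = m$b, lo = m$norm$lo, hi = m$norm$hi)
}

mlp_from_list <- function(x) {
  # weights are stored flat (column-major); shapes follow from the chain of
  # layer dimensions
  L <- length(x$b)
  d <- length(x$lo)
  W <- vector("list", L + 1L)
  for (l in seq_len(L + 1L)) {
    rows <- if (l <= L) length(x$b[[l]]) else 1L
    W[[l]] <- matrix(unlist(x$W[[l]]), rows, d)
    d <- rows
  }
  b <- lapply(x$b, unlist)
  structure(list(W = W, b = b,
                 norm = structure(list(lo = unlist(x$lo), hi = unlist(x$hi)),
                                  class = "rmm_normalizer")),
            class = "rmm_mlp")
}

#' Save / load a circuit model
#'
#' @param model an `rmm_circuit`.
#' @param path file path (JSON text).
#' @export
write_model <- function(model, path) {
  neurons <- lapply(model$neurons, function(ne) {
    out <- list(c_raw = ne$c_raw, leak_g_raw = ne$leak_g_raw,
                leak_b_raw = ne$leak_b_raw)
    if (!is.null(ne$intrinsic))
      out$intrinsic <- list(mlp = mlp_to_list(ne$intrinsic$mlp),
                            bank = ss_to_list(ne$intrinsic$bank))
    if (!is.null(ne$synapse)) {
      sy <- ne$synapse
      out$synapse <- if (sy$type == "mlp") {
        list(type = "mlp", mlp = mlp_to_list(sy$mlp), bank = ss_to_list(sy$bank))
      } else {
        list(type = "cond", g_raw = sy$g_raw, w_raw = sy$w_raw, b = sy$b,
             E_syn = sy$E_syn, hplus_lo = sy$hplus_lo, hplus_hi = sy$hplus_hi,
             bank = ss_to_list(sy$bank))
      }
    }
    out
  })
  obj <- list(format = "rmm_circuit", version = 1L, delta = model$delta,
              presyn = model$presyn, learn_c = model$learn_c,
              neurons = neurons)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "columnmajor", null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  if (!identical(x$format, "rmm_circuit"))
    stop_invalid("`", path, "` is not a serialized rmm_circuit")
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  neurons <- lapply(raw$neurons, function(nr) {
    ne <- list(c_raw = nr$c_raw, leak_g_raw = nr$leak_g_raw,
               leak_b_raw = nr$leak_b_raw, intrinsic = NULL, synapse = NULL)
    if (!is.null(nr$intrinsic))
      ne$intrinsic <- list(mlp = mlp_from_list(nr$intrinsic$mlp),
                           bank = ss_from_list(nr$intrinsic$bank))
    if (!is.null(nr$synapse)) {
      sy <- nr$synapse
      ne$synapse <- if (identical(sy$type, "mlp")) {
        list(type = "mlp", mlp = mlp_from_list(sy$mlp),
             bank = ss_from_list(sy$bank))
      } else {
        list(type = "cond", g_raw = sy$g_raw, w_raw = unlist(sy$w_raw),
             b = sy$b, E_syn = sy$E_syn, hplus_lo = unlist(sy$hplus_lo),
             hplus_hi = unlist(sy$hplus_hi), bank = ss_from_list(sy$bank))
      }
    }
    ne
  })
  structure(list(neurons = neurons, presyn = unlist(raw$presyn),
                 delta = raw$delta, learn_c = isTRUE(raw$learn_c),
                 spec = NULL),
            class = "rmm_circuit")
}
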
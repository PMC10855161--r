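#' Save a fitted model checkpoint
#'
#' Serializes the model (parameters, networks, class dictionary and a hash of
#' the encoder configuration) to a single file.
#'
#' @param model A \code{trustfuse_model}.
#' @param path Output file path (conventionally \code{.rds}).
#' @return Invisibly, \code{path}.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trustfuse_model"))
  # batch-ops caches are per-session scratch; drop them from the checkpoint
  model$ops <- NULL
  model$config_hash <- config_hash(model)
  saveRDS(model, path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path Path written by [save_model()].
#' @return The restored \code{trustfuse_model}.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "trustfuse_model")) stop("not a trustfuse checkpoint")
  stored <- model$config_hash
  model$config_hash <- NULL
  if (!is.null(stored) && !identical(stored, config_hash(model)))
    warning("checkpoint configuration hash mismatch")
  model$ops <- lapply(model$edges, function(e) new.env(parent = emptyenv()))
  model
}

# stable digest of the architecture-defining fields (no external digest
# package: serialize and fold into a short hex string)
config_hash <- function(model) {
  cfgs <- lapply(model$params, `[[`, "cfg")
  raw <- serialize(list(cfgs = cfgs, K = model$K,
                        omics = model$omics_names), NULL, version = 2)
  sum_ <- 0
  chunk <- as.integer(raw)
  for (i in seq_along(chunk))
    sum_ <- (sum_ * 31 + chunk[i]) %% 2147483647
  sprintf("%08x", sum_)
}
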
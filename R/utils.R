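# Small shared helpers.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Generators are pure functions of (spec, seed).
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_data <- function(...) stop(structure(class = c("svpnet_data_error", "error", "condition"),
                                          list(message = sprintf(...), call = sys.call(-1))))

stop_contract <- function(...) stop(structure(class = c("svpnet_contract_error", "error", "condition"),
                                              list(message = sprintf(...), call = sys.call(-1))))

is_binary_mask <- function(m) is.numeric(m) && all(m %in% c(0, 1))

# nearest-neighbour resize of a matrix (used to map masks between scales)
resize_nearest <- function(m, oh, ow) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(floor((seq_len(oh) - 0.5) * H / oh) + 1L, 1L), H)
  ci <- pmin(pmax(floor((seq_len(ow) - 0.5) * W / ow) + 1L, 1L), W)
  m[ri, ci, drop = FALSE]
}

# bilinear resize wrapper (matrix in, matrix out)
resize_bilinear <- function(m, oh, ow) {
  .cpp_resize_bilinear(as.matrix(m), as.integer(oh), as.integer(ow))
}

deep_copy_params <- function(params) lapply(params, function(p) p$value)

restore_params <- function(params, snapshot) {
  for (nm in names(snapshot)) params[[nm]]$value <- snapshot[[nm]]
  invisible(NULL)
}
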
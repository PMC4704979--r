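# Structured-text (YAML) configuration: programs, validity thresholds,
# difficulty ladders, starting records and responder models in one file.

#' Read a protocol configuration file
#'
#' Loads a YAML file describing a training protocol and returns ready-made
#' package objects. Recognized top-level keys (each optional; protocol
#' defaults fill gaps):
#'
#' * `program`: fields of [training_program()];
#' * `thresholds`: fields of [validity_thresholds()];
#' * `ladders`: per exercise type, `rate_steps` plus the base-config fields
#'   of [difficulty_ladder()]'s default;
#' * `responder`: fields of [responder_model()];
#' * `settings`: `user_mode` flag.
#'
#' @param path YAML file.
#' @return List with `program`, `thresholds`, `ladders`, `responder`,
#'   `user_mode`.
#' @export
read_protocol <- function(path) {
  raw <- yaml::read_yaml(path)
  program <- do.call(training_program, as_program_args(raw$program))
  thresholds <- do.call(validity_thresholds, raw$thresholds %||% list())
  ladders <- default_ladders()
  for (t in intersect(names(raw$ladders %||% list()), exercise_types())) {
    spec <- raw$ladders[[t]]
    steps <- spec$rate_steps %||% default_rate_steps(t)
    base <- spec$base %||% list()
    base$isi <- steps[[1]]
    cfg <- switch(t,
                  vs_wm = do.call(vswm_config, base),
                  op_nb = do.call(opnb_config, base),
                  d_nb = do.call(dnb_config, base))
    ladders[[t]] <- difficulty_ladder(t, rate_steps = steps, base_config = cfg,
                                      max_level = spec$max_level)
  }
  responder <- if (!is.null(raw$responder)) {
    args <- raw$responder
    if (!is.null(args$capacity) && length(args$capacity) > 1) {
      args$capacity <- unlist(args$capacity)
    }
    do.call(responder_model, args)
  }
  list(program = program, thresholds = thresholds, ladders = ladders,
       responder = responder,
       user_mode = isTRUE((raw$settings %||% list())$user_mode))
}

as_program_args <- function(x) {
  x <- x %||% list()
  if (!is.null(x$per_exercise_daily_minutes)) {
    x$per_exercise_daily_minutes <- unlist(x$per_exercise_daily_minutes)
  }
  x
}
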
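# Flat default configuration (dotted keys) resolved against the presets.
.default_config <- function() {
  list(paradigm = "ssa", tier = "rate", condition = "control",
       dt = 0.1, seed = 1L, out_dir = ".",
       rate.q = NA_real_, rate.w_ee = 1.1, rate.tau_d1 = 1500,
       rate.tau_d2 = 20, rate.r = 3, rate.a_dep = 0.5, rate.b_fac = 1,
       rate.alpha = 0.65, rate.use_proxy = TRUE,
       rate.regime_mode = "heaviside",
       spiking.n_e = 1600L, spiking.n_p = 200L, spiking.n_s = 200L,
       spiking.noise_sigma = 20, spiking.dt = 0.05,
       opto.amplitude = NA_real_)
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON) configuration file, validates it against the
#' known keys and merges it over the package defaults (the preset tables of
#' the paradigms). An empty file yields the pure defaults. Unknown keys and
#' out-of-range values are rejected with a descriptive error.
#'
#' @param path Configuration file path (`.yaml`/`.yml`/`.json`).
#' @return A named list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  user <- if (!length(txt) || !nzchar(paste(trimws(txt), collapse = ""))) {
    list()
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  }
  if (is.null(user)) user <- list()
  flat <- function(x, prefix = "") {
    out <- list()
    for (nm in names(x)) {
      key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
      if (is.list(x[[nm]])) out <- c(out, flat(x[[nm]], key))
      else out[[key]] <- x[[nm]]
    }
    out
  }
  user <- flat(user)
  defaults <- .default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, user)
  if (!cfg$paradigm %in% c("ssa", "ssa_simple", "fws", "tca", "pv_act"))
    stop("unknown paradigm: ", cfg$paradigm)
  if (!cfg$tier %in% c("rate", "spiking")) stop("unknown tier: ", cfg$tier)
  if (cfg$rate.r <= 0) stop("config value out of range: rate.r must be > 0")
  if (cfg$rate.tau_d1 <= 0 || cfg$rate.tau_d2 <= 0)
    stop("config value out of range: depression time constants must be > 0")
  if (cfg$dt <= 0 || cfg$spiking.dt <= 0)
    stop("config value out of range: dt must be > 0")
  structure(cfg, class = "run_config")
}

#' Save a run configuration
#'
#' @param cfg A `run_config` (or plain named list of known keys).
#' @param path Output path (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("writing YAML configs requires the 'yaml' package")
    yaml::write_yaml(unclass(cfg), path)
  }
  invisible(path)
}

#' Compare computed experiment values against registered targets
#'
#' Utility used by verification workflows: compares each computed value to
#' its registered reference with a per-target tolerance (relative for
#' deterministic targets, a z-band across seeds for stochastic ones).
#' Experiments that have not run are reported as `not_run`, not failed.
#'
#' @param computed Named list of computed values (`NULL`/missing = not run);
#'   stochastic entries may be numeric vectors over seeds.
#' @param targets data.frame with columns `id`, `value`, `type`
#'   (`"deterministic"` / `"stochastic"`).
#' @param rel_tol Relative tolerance for deterministic targets.
#' @param z_tol SD multiplier for stochastic targets.
#' @return data.frame with columns `id`, `target`, `value`, `status`.
#' @export
verify_targets <- function(computed, targets, rel_tol = 0.05, z_tol = 3) {
  rows <- lapply(seq_len(nrow(targets)), function(j) {
    id <- targets$id[j]; ref <- targets$value[j]; type <- targets$type[j]
    v <- computed[[id]]
    if (is.null(v) || !length(v) || all(is.na(v)))
      return(data.frame(id = id, target = ref, value = NA_real_,
                        status = "not_run"))
    if (type == "stochastic" && length(v) > 1) {
      m <- mean(v); s <- stats::sd(v)
      ok <- abs(m - ref) <= z_tol * max(s, .Machine$double.eps)
      data.frame(id = id, target = ref, value = m,
                 status = if (ok) "pass" else "fail")
    } else {
      m <- mean(v)
      ok <- abs(m - ref) <= rel_tol * abs(ref)
      data.frame(id = id, target = ref, value = m,
                 status = if (ok) "pass" else "fail")
    }
  })
  do.call(rbind, rows)
}
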
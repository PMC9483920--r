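# Extended-XYZ trajectory I/O and plain-text run configuration files.
# All files are in reduced units (lengths in sigma, energies in epsilon).

#' Write configurations as extended XYZ
#'
#' Each frame: particle count, a comment line with `key=value` metadata
#' (step, N, mu*, T*, U), then one `El x y z` line per particle. Positions
#' are written with 17 significant digits so write-then-read is the
#' identity to better than 1e-12.
#'
#' @param configs a [configuration()] or list of configurations.
#' @param path output file.
#' @param metadata optional list (one per frame) of named metadata values.
#' @param element element symbol written per particle.
#' @export
write_xyz <- function(configs, path, metadata = NULL, element = "P") {
  if (inherits(configs, "configuration") || is.matrix(configs))
    configs <- list(configs)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(configs)) {
    pos <- as_positions(configs[[f]])
    md <- if (!is.null(metadata) && length(metadata) >= f) metadata[[f]] else NULL
    comment <- if (is.null(md) || !length(md)) "frame"
               else paste(sprintf("%s=%s", names(md),
                                  vapply(md, format, "", digits = 17)),
                          collapse = " ")
    writeLines(as.character(nrow(pos)), con)
    writeLines(comment, con)
    if (nrow(pos))
      writeLines(sprintf("%s %.17g %.17g %.17g", element,
                         pos[, 1], pos[, 2], pos[, 3]), con)
  }
  invisible(path)
}

#' Read an extended XYZ trajectory
#'
#' @param path input file.
#' @param shell optional [shell_geometry()] attached to each frame.
#' @return List of [configuration()]s; each carries its comment-line
#'   metadata in attribute `"metadata"` (named character vector).
#' @export
read_xyz <- function(path, shell = NULL) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop(sprintf("xyz parse error at line %d: expected particle count", i))
    n <- as.integer(lines[i])
    if (i + 1 > length(lines))
      stop(sprintf("xyz parse error at line %d: missing comment line", i + 1))
    comment <- lines[i + 1]
    last <- i + 1 + n
    if (last > length(lines))
      stop(sprintf("xyz parse error in frame %d starting at line %d: %d atom lines expected, file ends early",
                   length(frames) + 1, i, n))
    pos <- matrix(numeric(0), ncol = 3)
    if (n > 0) {
      body <- lines[(i + 2):last]
      parts <- strsplit(trimws(body), "\\s+")
      bad <- which(vapply(parts, length, 0L) < 4)
      if (length(bad))
        stop(sprintf("xyz parse error at line %d: malformed atom line", i + 1 + bad[1]))
      pos <- t(vapply(parts, function(p)
        suppressWarnings(as.numeric(p[2:4])), numeric(3)))
      if (any(!is.finite(pos)))
        stop(sprintf("xyz parse error in frame %d: non-numeric coordinate",
                     length(frames) + 1))
    }
    cfg <- configuration(pos, shell = shell)
    md <- character(0)
    toks <- regmatches(comment, gregexpr("[^ ]+=[^ ]+", comment))[[1]]
    if (length(toks)) {
      kv <- strsplit(toks, "=", fixed = TRUE)
      md <- vapply(kv, `[`, "", 2)
      names(md) <- vapply(kv, `[`, "", 1)
    }
    attr(cfg, "metadata") <- md
    frames[[length(frames) + 1]] <- cfg
    i <- last + 1
  }
  frames
}

#' Write a GCMC observable log as CSV
#' @param run a `gcmc` object or its observables data.frame.
#' @param path output file.
#' @export
write_observables <- function(run, path) {
  obs <- if (inherits(run, "gcmc")) run$observables else run
  utils::write.csv(obs, path, row.names = FALSE)
  invisible(path)
}

# --- plain-text run configuration (TOML-style key = value sections) -------

default_run_config <- function() {
  list(
    potential = list(zeta = 0.05, lam = 1.5, kappa = 4.0),
    shell = list(R_inn = 6.0, R_out = 11.0),
    thermo = list(T_star = 0.35, mu_star = -2.17),
    moves = list(p_displacement = 0.95, delta = 0.5),
    schedule = list(n_equilibration = 1e6, n_production = 1e6,
                    sample_interval = 1e3, traj_interval = 0, seed = 1),
    analysis = list(cell_edge = 0.5, rho_iso = 0.4, r_bond = 1.5)
  )
}

#' Run configuration with the standard defaults
#'
#' Nested list of all simulation and analysis settings; the defaults are
#' the studied SALR state point (zeta = 0.05, lambda = 1.5, kappa = 4,
#' T* = 0.35, W = 5 shell, rho_iso = 0.4, r_bond = 1.5). Values round-trip
#' losslessly through the plain-text config file.
#'
#' @param ... named overrides per section, e.g.
#'   `run_config(thermo = list(mu_star = -2.2))`.
#' @return A `run_config` (nested named list).
#' @export
run_config <- function(...) {
  cfg <- default_run_config()
  over <- list(...)
  for (sec in names(over)) {
    if (!sec %in% names(cfg)) stop("unknown config section: ", sec)
    for (k in names(over[[sec]])) {
      if (!k %in% names(cfg[[sec]]))
        stop(sprintf("unknown config key: %s.%s", sec, k))
      cfg[[sec]][[k]] <- over[[sec]][[k]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration file
#'
#' Plain-text sectioned `key = value` format (TOML-like); numbers are
#' written with full precision so read-then-write round-trips exactly.
#'
#' @param cfg a [run_config()].
#' @param path file path.
#' @export
write_run_config <- function(cfg, path) {
  lines <- c("# salrshell run configuration (reduced units: sigma, epsilon)")
  for (sec in names(cfg)) {
    lines <- c(lines, sprintf("[%s]", sec))
    for (k in names(cfg[[sec]]))
      lines <- c(lines, sprintf("%s = %s", k,
                                format(cfg[[sec]][[k]], digits = 17)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- trimws(readLines(path))
  cfg <- default_run_config()
  sec <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (!sec %in% names(cfg))
        stop(sprintf("config parse error at line %d: unknown section [%s]", i, sec))
      next
    }
    if (!grepl("=", ln) || is.null(sec))
      stop(sprintf("config parse error at line %d: expected key = value", i))
    k <- trimws(sub("=.*", "", ln))
    v <- trimws(sub("^[^=]*=", "", ln))
    if (!k %in% names(cfg[[sec]]))
      stop(sprintf("config parse error at line %d: unknown key %s.%s", i, sec, k))
    cfg[[sec]][[k]] <- as.numeric(v)
  }
  structure(cfg, class = "run_config")
}
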
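#' Write a time-dependent vector field as an EnSight Gold case
#'
#' Writes an ASCII EnSight Gold case (the format used for deposited
#' stereo-PIV velocity datasets): a `.case` file, a structured-block
#' geometry file for the regular measurement-plane grid, and one
#' vector-per-node variable file per timestep.
#'
#' @param case_path Path of the `.case` file to write; companion files are
#'   placed next to it.
#' @param x,y Grid coordinate vectors (mm).
#' @param fields List over timesteps of `ny x nx x 3` velocity arrays
#'   (m/s); `NA`s are written as 0.
#' @param times Numeric timestep values (s).
#' @param varname Variable name in the case file.
#' @return Invisibly, `case_path`.
#' @export
write_ensight <- function(case_path, x, y, fields, times,
                          varname = "velocity") {
  stopifnot(length(fields) == length(times))
  dir <- dirname(case_path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- sub("\\.case$", "", basename(case_path))
  geo_file <- paste0(base, ".geo")
  var_pattern <- paste0(base, "_", varname, "_****.vec")

  nx <- length(x); ny <- length(y)
  fmt <- function(v) sprintf("%.8e", v)

  geo <- c("EnSight geometry file",
           "measurement-plane grid",
           "node id off",
           "element id off",
           "part",
           sprintf("%10d", 1L),
           "measurement plane",
           "block",
           sprintf("%10d%10d%10d", nx, ny, 1L),
           fmt(rep(x, times = ny)),
           fmt(rep(y, each = nx)),
           fmt(rep(0, nx * ny)))
  writeLines(geo, file.path(dir, geo_file))

  for (i in seq_along(fields)) {
    f <- fields[[i]]
    stopifnot(dim(f)[1] == ny, dim(f)[2] == nx, dim(f)[3] == 3)
    f[is.na(f)] <- 0
    # block node ordering: x index fastest -> transpose our (ny, nx) slabs
    vfile <- sub("\\*+", sprintf("%04d", i - 1L), var_pattern)
    writeLines(c(varname, "part", sprintf("%10d", 1L), "block",
                 fmt(as.vector(t(f[, , 1]))),
                 fmt(as.vector(t(f[, , 2]))),
                 fmt(as.vector(t(f[, , 3])))),
               file.path(dir, vfile))
  }

  case <- c("FORMAT",
            "type: ensight gold",
            "",
            "GEOMETRY",
            paste0("model: ", geo_file),
            "",
            "VARIABLE",
            paste0("vector per node: 1 ", varname, " ", var_pattern),
            "",
            "TIME",
            "time set: 1",
            paste0("number of steps: ", length(times)),
            "filename start number: 0",
            "filename increment: 1",
            "time values:",
            paste(fmt(times), collapse = " "))
  writeLines(case, case_path)
  invisible(case_path)
}

#' Read an EnSight Gold case
#'
#' Reads an ASCII EnSight Gold case with one structured-block part and one
#' vector-per-node variable over a time set (the dialect written by
#' [write_ensight()] and used by deposited stereo-PIV datasets). Binary
#' EnSight files are detected and rejected with an informative error;
#' missing referenced files are reported by name.
#'
#' @param case_path Path to the `.case` file.
#' @return List with grid vectors `x`, `y`, `z`, `times`, `varname`, and
#'   `velocity`, an `ny x nx x 3 x M` array.
#' @export
read_ensight <- function(case_path) {
  if (!file.exists(case_path)) stop("case file not found: ", case_path)
  dir <- dirname(case_path)
  lines <- readLines(case_path, warn = FALSE)
  grab <- function(key) {
    ln <- grep(paste0("^\\s*", key, "\\s*:"), lines, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub(paste0("^\\s*", key, "\\s*:"), "", ln[1]))
  }
  geo_file <- grab("model")
  if (is.null(geo_file)) stop("case file lists no geometry model")
  vline <- grep("^\\s*vector per node\\s*:", lines, value = TRUE)
  if (!length(vline)) stop("case file lists no vector-per-node variable")
  vparts <- strsplit(trimws(sub("^\\s*vector per node\\s*:", "", vline[1])),
                     "\\s+")[[1]]
  varname <- vparts[2]; var_pattern <- vparts[3]
  nsteps <- as.integer(grab("number of steps"))
  start <- as.integer(grab("filename start number") %||% "0")
  incr <- as.integer(grab("filename increment") %||% "1")
  it <- grep("^\\s*time values\\s*:?", lines)
  times <- as.numeric(unlist(strsplit(trimws(
    c(sub("^\\s*time values\\s*:?", "", lines[it]),
      lines[seq_len(length(lines)) > it])), "\\s+")))
  times <- times[is.finite(times)][seq_len(nsteps)]

  geo_path <- file.path(dir, geo_file)
  if (!file.exists(geo_path))
    stop("referenced geometry file missing: ", geo_file)
  head_raw <- readBin(geo_path, "raw", n = 160)
  if (any(head_raw == as.raw(0)) ||
      grepl("Binary", rawToChar(head_raw[head_raw > as.raw(0)]),
            ignore.case = TRUE))
    stop("binary EnSight geometry not supported (ASCII dialect only): ",
         geo_file)
  g <- readLines(geo_path, warn = FALSE)
  ib <- grep("^\\s*block", g)[1]
  if (is.na(ib)) stop("geometry file has no structured block part")
  dims <- as.integer(strsplit(trimws(g[ib + 1]), "\\s+")[[1]])
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  nn <- nx * ny * nz
  vals <- as.numeric(g[(ib + 2):(ib + 1 + 3 * nn)])
  xg <- vals[seq_len(nn)]; yg <- vals[nn + seq_len(nn)]
  zg <- vals[2 * nn + seq_len(nn)]
  x <- xg[seq_len(nx)]
  y <- yg[seq(1, nn, by = nx)][seq_len(ny)]

  vel <- array(NA_real_, c(ny, nx, 3, nsteps))
  wild <- regmatches(var_pattern, regexpr("\\*+", var_pattern))
  for (i in seq_len(nsteps)) {
    num <- start + (i - 1L) * incr
    vfile <- sub("\\*+", sprintf(paste0("%0", nchar(wild), "d"), num),
                 var_pattern)
    vpath <- file.path(dir, vfile)
    if (!file.exists(vpath))
      stop("referenced variable file missing: ", vfile)
    v <- readLines(vpath, warn = FALSE)
    ibv <- grep("^\\s*block", v)[1]
    if (is.na(ibv)) stop("variable file has no block section: ", vfile)
    nums <- as.numeric(v[(ibv + 1):(ibv + 3 * nn)])
    for (k in 1:3) {
      comp <- nums[(k - 1) * nn + seq_len(nn)]
      vel[, , k, i] <- t(matrix(comp, nrow = nx, ncol = ny))
    }
  }
  list(x = x, y = y, z = zg[1], times = times, varname = varname,
       velocity = vel)
}

#' Treat an EnSight dataset as a phase-averaged cycle
#'
#' Deposited stereo-PIV datasets store already phase-averaged velocity
#' fields, one timestep per phase; this wraps them as an
#' `aneupiv_phase_cycle` (single realization, no per-phase standard
#' deviations) so that all metrics apply.
#'
#' @param ens Result of [read_ensight()].
#' @return An `aneupiv_phase_cycle`.
#' @export
ensight_to_phase_cycle <- function(ens) {
  M <- dim(ens$velocity)[4]
  Tdur <- if (M >= 2) (ens$times[2] - ens$times[1]) * M else 1
  structure(list(mean = ens$velocity, sd = NULL, x = ens$x, y = ens$y,
                 n_cycles = 1L, n_phases = M,
                 phase_duration = Tdur / M, cycle_duration = Tdur),
            class = "aneupiv_phase_cycle")
}

#' Export a phase-averaged cycle as EnSight Gold
#'
#' One timestep per phase, matching the deposited-dataset layout.
#'
#' @param pac An `aneupiv_phase_cycle`.
#' @param case_path Output `.case` path.
#' @return Invisibly, `case_path`.
#' @export
phase_cycle_to_ensight <- function(pac, case_path) {
  fields <- lapply(seq_len(pac$n_phases),
                   function(p) pac$mean[, , , p, drop = TRUE])
  write_ensight(case_path, pac$x, pac$y, fields,
                times = (seq_len(pac$n_phases) - 1) * pac$phase_duration)
}
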
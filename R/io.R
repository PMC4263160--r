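#' Write a configuration as extended XYZ
#'
#' One record per particle (species `ELL`) with the particle centre, or, with
#' `sites = TRUE`, additionally one record per charge site (`QP` at `+d`,
#' `QM` at `-d`) for visualization. The comment line carries the run
#' parameters as `key=value` pairs (`box`, `R`, `rho`, `d`, `gamma`, `mode`,
#' `cycle`), so a written file is self-describing and can be classified
#' without extra flags.
#'
#' @param state an [system_state()].
#' @param file path to write to.
#' @param sites also write the two charge-site records per particle.
#' @param cycle cycle index stored in the header.
#' @param digits printed coordinate precision.
#' @return `file`, invisibly.
#' @export
write_xyz <- function(state, file, sites = FALSE, cycle = 0L, digits = 10) {
  sh <- state$shape
  n <- nrow(state$centres)
  fmt <- sprintf("%%.%dg", digits)
  hdr <- sprintf(
    'box="%s %s %s" R=%s rho=%s d=%s gamma=%s mode=%s cycle=%d',
    sprintf(fmt, state$box[1]), sprintf(fmt, state$box[2]),
    sprintf(fmt, state$box[3]), sprintf(fmt, sh$R), sprintf(fmt, sh$rho),
    sprintf(fmt, sh$d), sprintf(fmt, state$gamma), state$mode, cycle)
  rec <- sprintf(paste0("ELL ", fmt, " ", fmt, " ", fmt),
                 state$centres[, 1], state$centres[, 2], state$centres[, 3])
  if (sites) {
    qp <- sprintf(paste0("QP ", fmt, " ", fmt, " ", fmt),
                  state$centres[, 1], state$centres[, 2],
                  state$centres[, 3] + sh$d)
    qm <- sprintf(paste0("QM ", fmt, " ", fmt, " ", fmt),
                  state$centres[, 1], state$centres[, 2],
                  state$centres[, 3] - sh$d)
    rec <- c(rec, qp, qm)
  }
  writeLines(c(as.character(length(rec)), hdr, rec), file)
  invisible(file)
}

#' Read a configuration from extended XYZ
#'
#' Parses a file written by [write_xyz()] (site records `QP`/`QM` are
#' skipped; the particle centres and the header parameters fully determine
#' the state).
#'
#' @param file path to read.
#' @return An `elltube_state`.
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  if (length(lines) < 2) stop("malformed XYZ: fewer than 2 lines")
  nrec <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(nrec)) stop("malformed XYZ at line 1: record count expected")
  hdr <- lines[2]
  getval <- function(key, quoted = FALSE) {
    pat <- if (quoted) sprintf('%s="([^"]*)"', key) else
      sprintf('%s=([^ ]+)', key)
    m <- regmatches(hdr, regexec(pat, hdr))[[1]]
    if (length(m) < 2) stop(sprintf("malformed XYZ header: missing %s", key))
    m[2]
  }
  box <- as.numeric(strsplit(getval("box", quoted = TRUE), "[ ]+")[[1]])
  R <- as.numeric(getval("R"))
  rho <- as.numeric(getval("rho"))
  gamma <- as.numeric(getval("gamma"))
  mode <- getval("mode")
  body <- lines[seq(3, length.out = nrec)]
  toks <- strsplit(trimws(body), "[ \t]+")
  bad <- which(vapply(toks, length, integer(1)) != 4)
  if (length(bad) > 0)
    stop(sprintf("malformed XYZ record at line %d", 2 + bad[1]))
  species <- vapply(toks, `[[`, character(1), 1)
  keep <- species == "ELL"
  xyz <- t(vapply(toks[keep], function(t) as.numeric(t[2:4]), numeric(3)))
  if (any(!is.finite(xyz))) stop("malformed XYZ: non-numeric coordinate")
  system_state(xyz, spheroid_shape(rho, R), box, gamma = gamma, mode = mode,
               check = FALSE)
}

#' Write a trajectory as multi-frame extended XYZ
#'
#' @param traj an `elltube_trajectory`.
#' @param file path to write to.
#' @param sites include charge-site records.
#' @export
write_xyz_trajectory <- function(traj, file, sites = FALSE) {
  st <- traj$final_state
  con <- file(file, "w")
  on.exit(close(con))
  for (f in seq_along(traj$snapshots)) {
    tmp <- tempfile()
    write_xyz(system_state(traj$snapshots[[f]], st$shape, st$box,
                           gamma = st$gamma, mode = st$mode, check = FALSE),
              tmp, sites = sites, cycle = traj$cycle[f])
    writeLines(readLines(tmp), con)
    unlink(tmp)
  }
  invisible(file)
}

#' Run metadata as JSON
#'
#' Serializes all parameters of a trajectory (shape, box, coupling, mode,
#' MC parameters, seed) for reproducibility: every artifact is regenerable
#' from its metadata.
#'
#' @param traj an `elltube_trajectory`.
#' @param file optional path; when `NULL` the JSON string is returned.
#' @export
run_metadata <- function(traj, file = NULL) {
  st <- traj$final_state
  meta <- list(
    package = "elltube",
    version = as.character(utils::packageVersion("elltube")),
    n = nrow(st$centres),
    shape = list(R = st$shape$R, rho = st$shape$rho, d = st$shape$d),
    box = st$box,
    phi = volume_fraction(st),
    gamma = st$gamma,
    mode = st$mode,
    mc = traj$params,
    units = "lengths in R, energies in kT")
  js <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(file)
}
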
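# FCIDUMP (Molpro dialect) serialization of the active-space Hamiltonian.

#' Write an active Hamiltonian to FCIDUMP
#'
#' Standard Molpro dialect: `&FCI NORB=..,NELEC=..,MS2=..` header with
#' `ORBSYM`/`ISYM`, two-electron records `(pq|rs) p q r s` over the
#' eight-fold-unique index set, one-electron records `h_pq p q 0 0`, and
#' the scalar core energy as the zero-index record.
#'
#' @param ham a `qc_active_ham`
#' @param path output file
#' @param thresh integrals with magnitude below this are not written
#' @return `path`, invisibly
#' @export
write_fcidump <- function(ham, path, thresh = 1e-14) {
  n <- ham$norb
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf(" &FCI NORB=%d,NELEC=%d,MS2=0,", n, ham$nelec),
    paste0("  ORBSYM=", paste(rep("1,", n), collapse = "")),
    "  ISYM=1,",
    " &END"), con)
  out <- character(0)
  for (p in seq_len(n)) for (q in seq_len(p)) {
    pq <- (p - 1) * p / 2 + q
    for (r in seq_len(p)) for (s in seq_len(r)) {
      rs <- (r - 1) * r / 2 + s
      if (rs > pq) next
      v <- ham$eri[p, q, r, s]
      if (abs(v) > thresh)
        out <- c(out, sprintf("%23.16E %4d %4d %4d %4d", v, p, q, r, s))
    }
  }
  for (p in seq_len(n)) for (q in seq_len(p)) {
    v <- ham$h[p, q]
    if (abs(v) > thresh)
      out <- c(out, sprintf("%23.16E %4d %4d %4d %4d", v, p, q, 0L, 0L))
  }
  out <- c(out, sprintf("%23.16E %4d %4d %4d %4d", ham$e_core, 0L, 0L, 0L, 0L))
  writeLines(out, con)
  invisible(path)
}

#' Read an FCIDUMP file
#'
#' @param path FCIDUMP file (Molpro dialect, as written by
#'   [write_fcidump()])
#' @return a `qc_active_ham`
#' @export
read_fcidump <- function(path) {
  lines <- readLines(path)
  hdr_end <- grep("&END|/\\s*$", lines)[1]
  if (is.na(hdr_end)) stop("malformed FCIDUMP: no &END header terminator")
  hdr <- paste(lines[seq_len(hdr_end)], collapse = " ")
  getval <- function(key) {
    m <- regmatches(hdr, regexec(paste0(key, "\\s*=\\s*([0-9]+)"), hdr))[[1]]
    if (length(m) < 2) stop("FCIDUMP header missing ", key)
    as.integer(m[2])
  }
  n <- getval("NORB")
  nelec <- getval("NELEC")
  h <- matrix(0, n, n)
  eri <- array(0, rep(n, 4))
  e_core <- 0
  body <- lines[-seq_len(hdr_end)]
  body <- body[nzchar(trimws(body))]
  for (ln in body) {
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    v <- as.numeric(sub("D", "E", tok[1], ignore.case = TRUE))
    idx <- as.integer(tok[2:5])
    p <- idx[1]; q <- idx[2]; r <- idx[3]; s <- idx[4]
    if (p == 0) {
      e_core <- v
    } else if (r == 0) {
      h[p, q] <- v; h[q, p] <- v
    } else {
      for (ii in list(c(p, q, r, s), c(q, p, r, s), c(p, q, s, r),
                      c(q, p, s, r), c(r, s, p, q), c(s, r, p, q),
                      c(r, s, q, p), c(s, r, q, p)))
        eri[ii[1], ii[2], ii[3], ii[4]] <- v
    }
  }
  structure(list(norb = n, nelec = nelec, h = h, eri = eri,
                 e_core = e_core),
            class = "qc_active_ham")
}
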
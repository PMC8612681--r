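# Plain-text formats: circuit declarations, time-course CSV, length CSV.
#
# CSV dialect: comma-separated, UTF-8, header row, '.' decimal; lengths are
# integers; concentrations nM; time seconds (time courses) or hours (length
# tables).

#' Write a circuit declaration file
#'
#' Human-readable, lossless text format: one `domain` line per base domain
#' (name, length, optional mismatch/bridge flags) and one `strand` line per
#' strand (name, ordered domain labels with `*` suffix, labels, hairpin
#' annotations `protected|guard|mode|loop`).
#'
#' @param strands Named list of [strand()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_circuit_text <- function(strands, path) {
  doms <- list()
  for (s in strands) for (d in s$domains) {
    base <- d; base$is_complement <- FALSE
    doms[[domain_label(base)]] <- base
  }
  lines <- character()
  for (lbl in sort(names(doms))) {
    d <- doms[[lbl]]
    ln <- sprintf("domain %s %d", d$name, d$length_nb)
    if (d$mismatch_nb > 0L) ln <- paste0(ln, " mismatch=", d$mismatch_nb)
    if (d$bridge) ln <- paste0(ln, " bridge")
    lines <- c(lines, ln)
  }
  for (s in strands) {
    ln <- paste("strand", s$name,
                paste(vapply(s$domains, domain_label, character(1)), collapse = " "))
    if (length(s$labels) > 0L) {
      ln <- paste0(ln, " labels=", paste(s$labels, collapse = ","))
    }
    for (hp in s$hairpins) {
      ln <- paste0(ln, " hairpin=", paste(hp$protected, collapse = ","), "|",
                   hp$guard, "|", hp$mode, "|", paste(hp$loop, collapse = ","))
    }
    lines <- c(lines, ln)
  }
  writeLines(lines, path)
  invisible(path)
}

parse_domain_label <- function(lbl, doms) {
  star <- grepl("\\*$", lbl)
  base <- sub("\\*$", "", lbl)
  if (!base %in% names(doms)) {
    stop("strand references undeclared domain '", base, "'", call. = FALSE)
  }
  d <- doms[[base]]
  if (star) d <- complement(d)
  d
}

#' Read a circuit declaration file
#'
#' @param path File written by [write_circuit_text()].
#' @return Named list of [strand()] objects.
#' @export
read_circuit_text <- function(path) {
  lines <- readLines(path)
  doms <- list()
  strands <- list()
  for (li in seq_along(lines)) {
    ln <- trimws(lines[li])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    tok <- strsplit(ln, "\\s+")[[1L]]
    if (tok[1L] == "domain") {
      if (length(tok) < 3L) {
        stop(sprintf("parse error at line %d: domain needs name and length", li),
             call. = FALSE)
      }
      mm <- 0L; br <- FALSE
      for (t in tok[-(1:3)]) {
        if (startsWith(t, "mismatch=")) mm <- as.integer(sub("mismatch=", "", t))
        else if (t == "bridge") br <- TRUE
        else stop(sprintf("parse error at line %d: unknown token '%s'", li, t),
                  call. = FALSE)
      }
      d <- domain(tok[2L], as.integer(tok[3L]), mismatch_nb = mm, bridge = br)
      doms[[domain_label(d)]] <- d
    } else if (tok[1L] == "strand") {
      if (length(tok) < 3L) {
        stop(sprintf("parse error at line %d: strand needs name and domains", li),
             call. = FALSE)
      }
      nm <- tok[2L]
      dom_tok <- character(); labels <- character(); hps <- list()
      for (t in tok[-(1:2)]) {
        if (startsWith(t, "labels=")) {
          labels <- strsplit(sub("labels=", "", t), ",")[[1L]]
        } else if (startsWith(t, "hairpin=")) {
          parts <- strsplit(sub("hairpin=", "", t), "|", fixed = TRUE)[[1L]]
          if (length(parts) < 3L) {
            stop(sprintf("parse error at line %d: malformed hairpin", li),
                 call. = FALSE)
          }
          loop <- if (length(parts) >= 4L && nzchar(parts[4L])) {
            strsplit(parts[4L], ",")[[1L]]
          } else character()
          hps[[length(hps) + 1L]] <- hairpin(
            protected = strsplit(parts[1L], ",")[[1L]],
            guard = parts[2L], mode = parts[3L], loop = loop
          )
        } else {
          dom_tok <- c(dom_tok, t)
        }
      }
      strands[[nm]] <- strand(nm, lapply(dom_tok, parse_domain_label, doms = doms),
                              labels = labels, hairpins = hps)
    } else {
      stop(sprintf("parse error at line %d, column 1: unknown record '%s'",
                   li, tok[1L]), call. = FALSE)
    }
  }
  strands
}

#' Write a time course to CSV
#'
#' Header row `time_s` then canonical species labels (plus any fluorescence
#' columns), one row per grid point.
#'
#' @param tc A `dsd_timecourse` (or plain tibble with `time_s`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  utils::write.csv(as.data.frame(tc), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a time course CSV
#'
#' @param path File written by [write_timecourse()].
#' @return Tibble with `time_s` and species columns.
#' @export
read_timecourse <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  tibble::as_tibble(df)
}

#' Write a length-distribution table to CSV
#'
#' Schema `(time_h, species, length, count)` (a `seed` column is kept if
#' present); the same schema accepts hand-entered TEM count tables.
#'
#' @param d Tibble of length counts.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lengths <- function(d, path) {
  keep <- intersect(c("seed", "species", "time_h", "length", "count"), names(d))
  utils::write.csv(as.data.frame(d[, keep]), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a length-distribution CSV
#'
#' @param path File with columns `(time_h, species, length, count)`.
#' @return Tibble.
#' @export
read_lengths <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("time_h", "species", "length", "count")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("length table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$length <- as.integer(df$length)
  tibble::as_tibble(df)
}
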
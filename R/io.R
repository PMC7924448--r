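# Plain-text serialization: XYZ particle snapshots, flat key-value run
# configs, CSV statistics.

#' Write / read a particle system as XYZ text
#'
#' Standard XYZ layout: particle count, comment line, then one
#' `<label> x y z` row per particle. The label encodes the domain
#' (`D1`, `D2`, ...), so the domain structure round-trips.
#'
#' @param domains list of `P x 3` position matrices.
#' @param file path.
#' @param comment comment line content.
#' @return `write_xyz()` returns the path invisibly; `read_xyz()` a list of
#'   position matrices.
#' @export
write_xyz <- function(domains, file, comment = "specflow particle system") {
  n <- sum(vapply(domains, nrow, integer(1)))
  lines <- c(as.character(n), comment)
  for (d in seq_along(domains)) {
    m <- domains[[d]]
    if (nrow(m) > 0) {
      lines <- c(lines, sprintf("D%d %.17g %.17g %.17g",
                                d, m[, 1], m[, 2], m[, 3]))
    }
  }
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  n <- as.integer(lines[1L])
  rows <- strsplit(trimws(lines[seq_len(n) + 2L]), "\\s+")
  lab <- vapply(rows, `[[`, character(1), 1L)
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  lapply(unique(lab), function(l) {
    unname(xyz[lab == l, , drop = FALSE])
  })
}

#' Flat key-value run configuration files
#'
#' One `key = value` pair per line; `#` starts a comment. Values are
#' coerced to numeric or logical where possible; comma-separated values
#' become vectors.
#'
#' @param config named list.
#' @param file path.
#' @return `write_run_config()` the path invisibly; `read_run_config()` a
#'   named list.
#' @export
write_run_config <- function(config, file) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste0(k, " = ", paste(format(v, digits = 17), collapse = ","))
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(file) {
  lines <- readLines(file)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  out <- list()
  for (ln in lines) {
    k <- trimws(sub("=.*$", "", ln))
    v <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(v, ",")[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) {
      out[[k]] <- num
    } else if (all(toupper(parts) %in% c("TRUE", "FALSE"))) {
      out[[k]] <- as.logical(toupper(parts))
    } else {
      out[[k]] <- parts
    }
  }
  out
}

#' Write per-sweep statistics as CSV
#'
#' @param stats data.frame (e.g. the `stats` element of [run_mc()]).
#' @param file path.
#' @return the path, invisibly.
#' @export
write_stats_csv <- function(stats, file) {
  write.csv(stats, file, row.names = FALSE)
  invisible(file)
}
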
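# Readers and writers: delimited text tables with '#' metadata headers.
# Every writer's output is re-readable by the matching reader.

write_header <- function(meta, path) {
  lines <- character(0)
  for (nm in names(meta)) {
    if (!is.null(meta[[nm]])) {
      lines <- c(lines, paste0("# ", nm, ": ", meta[[nm]]))
    }
  }
  writeLines(lines, path)
  lines
}

read_header <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  meta
}

#' Write / read a peak list
#'
#' Two-column delimited text (`mz`, `intensity`) with `# key: value`
#' metadata header lines (sequence, precursor charge, seed).
#'
#' @param peaks Peak-list tibble.
#' @param path File path.
#' @return `write_peaklist()` returns `path` invisibly; `read_peaklist()`
#'   returns the tibble with metadata restored as attributes.
#' @export
write_peaklist <- function(peaks, path) {
  meta <- list(sequence = attr(peaks, "sequence"),
               precursor_charge = attr(peaks, "precursor_charge"),
               seed = attr(peaks, "seed"))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta)) {
    if (!is.null(meta[[nm]])) {
      writeLines(paste0("# ", nm, ": ", meta[[nm]]), con)
    }
  }
  utils::write.table(
    data.frame(mz = sprintf("%.6f", peaks$mz),
               intensity = sprintf("%.6g", peaks$intensity)),
    con, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_peaklist
#' @export
read_peaklist <- function(path) {
  meta <- read_header(path)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  out <- tibble::tibble(mz = as.numeric(tab$mz),
                        intensity = as.numeric(tab$intensity))
  if (!is.null(meta$sequence)) attr(out, "sequence") <- meta$sequence
  if (!is.null(meta$precursor_charge)) {
    attr(out, "precursor_charge") <- as.integer(meta$precursor_charge)
  }
  if (!is.null(meta$seed)) attr(out, "seed") <- as.integer(meta$seed)
  out
}

#' Write / read a theoretical fragment table
#'
#' Delimited text with 6-decimal masses; the composition list-column is
#' rendered as a formula string and re-parsed on read.
#'
#' @param fragments Output of [enumerate_fragments()].
#' @param path File path.
#' @export
write_fragment_table <- function(fragments, path) {
  tab <- fragments
  tab$composition <- vapply(tab$composition, format, "")
  tab$neutral_mass <- sprintf("%.6f", tab$neutral_mass)
  tab$mz <- sprintf("%.6f", tab$mz)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragment_table
#' @export
read_fragment_table <- function(path) {
  tab <- tibble::as_tibble(
    utils::read.delim(path, stringsAsFactors = FALSE)
  )
  tab$base_loss <- as.integer(tab$base_loss)
  tab$composition <- lapply(tab$composition, parse_formula)
  tab
}

#' Write / read an assignment table
#'
#' @param assignments Assignment tibble from [match_fragments()].
#' @param path File path.
#' @export
write_assignments <- function(assignments, path) {
  tab <- assignments
  for (col in c("neutral_mass", "mz_theo", "mz_obs")) {
    tab[[col]] <- sprintf("%.6f", tab[[col]])
  }
  tab$mass_error_ppm <- sprintf("%.4f", tab$mass_error_ppm)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  tab <- tibble::as_tibble(utils::read.delim(path,
                                             stringsAsFactors = FALSE))
  tab$base_loss <- as.integer(tab$base_loss)
  tab
}

#' Write / read a cleavage-yield table
#'
#' @param yields A `cleavage_yields` table.
#' @param path File path.
#' @export
write_yields <- function(yields, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# sequence: ", attr(yields, "sequence")),
    paste0("# n: ", attr(yields, "n"))
  ), con)
  tab <- as.data.frame(yields)
  for (col in c("yield_c", "yield_y", "yield")) {
    tab[[col]] <- sprintf("%.6f", tab[[col]])
  }
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_yields
#' @export
read_yields <- function(path) {
  meta <- read_header(path)
  tab <- tibble::as_tibble(utils::read.delim(path, comment.char = "#",
                                             stringsAsFactors = FALSE))
  attr(tab, "sequence") <- meta$sequence
  attr(tab, "n") <- if (is.null(meta$n)) NA_integer_ else
    suppressWarnings(as.integer(meta$n))
  class(tab) <- c("cleavage_yields", class(tab))
  tab
}

#' Write ground truth as a structured-text sidecar
#'
#' @param truth The `truth` element of a [simulate_cad_spectrum()] result.
#' @param path File path (YAML).
#' @export
write_ground_truth <- function(truth, path) {
  obj <- list(
    sequence = truth$sequence, n = truth$n, n_ions = truth$n_ions,
    seed = truth$seed, gamma = truth$gamma,
    n_survived = truth$n_survived,
    site_counts = lapply(seq_len(nrow(truth$site_counts)), function(i) {
      as.list(truth$site_counts[i, ])
    }),
    species = lapply(seq_len(nrow(truth$species)), function(i) {
      x <- as.list(truth$species[i, ])
      x$base_loss <- if (is.na(x$base_loss)) "NA" else x$base_loss
      x
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$site_counts <- dplyr::bind_rows(lapply(obj$site_counts,
                                             tibble::as_tibble))
  obj$species <- dplyr::bind_rows(lapply(obj$species, function(x) {
    x$base_loss <- if (identical(x$base_loss, "NA")) NA_integer_ else
      as.integer(x$base_loss)
    tibble::as_tibble(x)
  }))
  obj
}

#' Run configuration
#'
#' A serializable bundle of everything a pipeline run depends on; validated
#' up front and echoed into the output directory so a run can be repeated.
#'
#' @param sequence Sequence string.
#' @param n Precursor charge.
#' @param ion_types Ion types to enumerate.
#' @param tol_ppm Matching tolerance (> 0).
#' @param gamma,n_ions,seed Simulator settings.
#' @param noise Noise settings, see [noise_default()].
#' @param out_dir Output directory.
#' @return A validated `run_config` list.
#' @export
run_config <- function(sequence, n, ion_types = c("c", "y"), tol_ppm = 3,
                       gamma = 2.75, n_ions = 1e5, seed = 1,
                       noise = noise_default(), out_dir = ".") {
  if (tol_ppm <= 0) stop("tol_ppm must be > 0", call. = FALSE)
  seq <- parse_rna(sequence) # errors on unparseable input
  if (n < 1 || n > length(seq) - 1) {
    stop("precursor charge out of range for this sequence", call. = FALSE)
  }
  structure(
    list(sequence = as.character(seq), n = n, ion_types = ion_types,
         tol_ppm = tol_ppm, gamma = gamma, n_ions = n_ions, seed = seed,
         noise = noise, out_dir = out_dir),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path File path (YAML).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  run_config(obj$sequence, obj$n, ion_types = unlist(obj$ion_types),
             tol_ppm = obj$tol_ppm, gamma = obj$gamma, n_ions = obj$n_ions,
             seed = obj$seed, noise = obj$noise,
             out_dir = obj$out_dir %||% ".")
}

#' Text cleavage map
#'
#' Renders a cleavage map in the style of the classic figure annotation:
#' the sequence with per-site c (above) and y (below) tick marks scaled by
#' yield, guanosine sites highlighted.
#'
#' @param yields A `cleavage_yields` table.
#' @param threshold Minimum percent yield for a tick.
#' @return A character vector of lines (printable with `cat(..., sep =
#'   "\n")`).
#' @export
cleavage_map <- function(yields, threshold = 1) {
  seq <- parse_rna(attr(yields, "sequence"))
  tokens <- ifelse(nchar(seq$residues) > 1,
                   paste0("[", seq$residues, "]"), seq$residues)
  width <- nchar(tokens)
  pos <- cumsum(width)
  n <- length(seq)
  line_seq <- paste(tokens, collapse = "")
  mark <- function(v) {
    out <- strrep(" ", nchar(line_seq))
    for (k in seq_len(n - 1)) {
      if (v[k] >= threshold) {
        ch <- if (v[k] >= 10) "#" else "|"
        substr(out, pos[k], pos[k]) <- ch
      }
    }
    out
  }
  gline <- strrep(" ", nchar(line_seq))
  for (k in which(yields$g_site)) {
    substr(gline, pos[k], pos[k]) <- "G"
  }
  c(paste0("c   ", mark(yields$yield_c)),
    paste0("5'  ", line_seq, "  3'"),
    paste0("y   ", mark(yields$yield_y)),
    paste0("G?  ", gline))
}
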
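# Web-style static report: index page, per-chromosome overview pages,
# per-region probe-classification pages, karyogram and cluster heatmap.
# Pure presentation — every number shown is taken from the analysis
# artifacts, and regeneration from the same result is byte-identical when
# timestamps are suppressed.

call_colours <- c(`-2` = "#00b3b3", `-1` = "#e08283", `0` = "#d5d8dc",
                  `1` = "#7dcea0", `2` = "#e6c400")

browser_url <- function(build, chrom, start, end) {
  # start/end printed 1-based inclusive
  host <- switch(build,
                 GRCh38 = "https://www.ensembl.org",
                 GRCh37 = "https://grch37.ensembl.org",
                 NCBI36 = "https://may2009.archive.ensembl.org",
                 NULL)
  if (is.null(host)) return(NULL)
  sprintf("%s/Homo_sapiens/Location/View?r=%s:%d-%d",
          host, chrom, start + 1L, end)
}

html_page <- function(title, body, timestamp = NULL) {
  foot <- if (!is.null(timestamp)) {
    sprintf("<footer><small>generated %s</small></footer>", timestamp)
  } else ""
  paste0(
    "<!DOCTYPE html>\n<html><head><meta charset='utf-8'>\n",
    sprintf("<title>%s</title>\n", title),
    "<style>body{font-family:sans-serif;margin:2em;}",
    "table{border-collapse:collapse;}",
    "td,th{border:1px solid #bbb;padding:2px 6px;font-size:12px;}",
    ".mri{outline:2px solid #c0392b;outline-offset:-2px;}",
    "</style></head>\n<body>\n",
    sprintf("<h1>%s</h1>\n", title),
    body, "\n", foot, "</body></html>\n")
}

html_table <- function(df) {
  if (nrow(df) == 0) return("<p>(none)</p>")
  fmt <- function(v) {
    if (is.numeric(v) && !is.integer(v)) format(round(v, 4), trim = TRUE) else as.character(v)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  head <- paste0("<tr>", paste0("<th>", names(df), "</th>", collapse = ""), "</tr>")
  rows <- apply(cells, 1, function(r) {
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>")
  })
  paste0("<table>\n", head, "\n", paste(rows, collapse = "\n"), "\n</table>")
}

region_page_name <- function(direction, chrom, cri) {
  sprintf("region_%s_chr%s_%d.html", direction, chrom, cri)
}

#' Per-region probe classification page
#'
#' Writes the HTML page showing the probe x sample call grid of one CRI
#' (green gain, red loss, grey normal, yellow high-level gain, cyan
#' high-level loss), with the MRI probes outlined and a hyperlink to an
#' external genome browser for the region's span. Unknown genome builds
#' omit the link with a warning.
#'
#' @param cri_row One row of a CRI tibble (with `chrom`, `direction`,
#'   `cri`, `probe_first`, `probe_last`, `start`, `end`).
#' @param mri_rows The CRI's MRI rows.
#' @param calls A `swat_calls` table.
#' @param dir Output directory.
#' @param build Genome build label for the browser link.
#' @param timestamp Optional timestamp string (omit for reproducible bytes).
#' @return The written file name, invisibly.
#' @export
region_page <- function(cri_row, mri_rows, calls, dir, build = "GRCh37",
                        timestamp = NULL) {
  assert_calls(calls)
  idx <- which(calls$chrom == cri_row$chrom)
  idx <- idx[cri_row$probe_first:cri_row$probe_last]
  samples <- sample_ids(calls)
  grid <- as.matrix(as.data.frame(calls)[idx, samples, drop = FALSE])
  in_mri <- rep(FALSE, length(idx))
  for (k in seq_len(nrow(mri_rows))) {
    rel <- (mri_rows$probe_first[k]:mri_rows$probe_last[k]) -
      cri_row$probe_first + 1L
    in_mri[rel] <- TRUE
  }
  head <- paste0("<tr><th>probe</th><th>position</th>",
                 paste0("<th>", samples, "</th>", collapse = ""), "</tr>")
  rows <- vapply(seq_along(idx), function(i) {
    cls <- if (in_mri[i]) " class='mri'" else ""
    tds <- paste0(vapply(samples, function(s) {
      v <- grid[i, s]
      sprintf("<td style='background:%s'>%d</td>",
              call_colours[[as.character(v)]], v)
    }, character(1)), collapse = "")
    sprintf("<tr%s><td>%s</td><td>%s:%d</td>%s</tr>", cls,
            calls$probe_id[idx[i]], cri_row$chrom,
            calls$start[idx[i]] + 1L, tds)
  }, character(1))
  url <- browser_url(build, cri_row$chrom, cri_row$start, cri_row$end)
  link <- if (is.null(url)) {
    rlang::warn(sprintf("Unknown genome build '%s'; browser links omitted.", build))
    ""
  } else {
    sprintf("<p><a href='%s'>View %s:%d-%d in the genome browser</a></p>",
            url, cri_row$chrom, cri_row$start + 1L, cri_row$end)
  }
  legend <- paste0(
    "<p>", paste(sprintf(
      "<span style='background:%s;padding:0 8px;'>&nbsp;</span> %s",
      call_colours, c("high-level loss", "loss", "normal", "gain",
                      "high-level gain")), collapse = " &middot; "), "</p>")
  body <- paste0(
    sprintf("<p>%s CRI #%d on chromosome %s, probes %d-%d (MRI outlined).</p>",
            cri_row$direction, cri_row$cri, cri_row$chrom,
            cri_row$probe_first, cri_row$probe_last),
    link, legend,
    "<table>\n", head, "\n", paste(rows, collapse = "\n"), "\n</table>",
    "<p><a href='index.html'>back to index</a></p>")
  fn <- region_page_name(cri_row$direction, cri_row$chrom, cri_row$cri)
  title <- sprintf("%s CRI %d (chr%s)", cri_row$direction, cri_row$cri,
                   cri_row$chrom)
  writeLines(html_page(title, body, timestamp), file.path(dir, fn))
  invisible(fn)
}

save_figure <- function(plot, path, width = 7, height = 5) {
  grDevices::png(path, width = width * 110, height = height * 110, res = 110,
                 type = "cairo")
  on.exit(grDevices::dev.off())
  print(plot)
}

#' Generate the web-style report
#'
#' Writes a self-contained output directory: `index.html`, one page and
#' overview figure per chromosome, one page per CRI (probe classification
#' grids with browser links), a karyogram, the cluster heatmap, every table
#' as TSV alongside the HTML, and an asset manifest. Region tables are
#' ordered by genome position and serially indexed consistently with the
#' overview plots; every region index in a table links to an existing
#' region page.
#'
#' @param result A `swat_result` from [swat_run()].
#' @param dir Output directory (created; existing files overwritten).
#' @param method Which segmentation method's results to render (default:
#'   the first).
#' @param timestamps Include generation timestamps (set `FALSE` for
#'   byte-reproducible output).
#' @return The manifest tibble (file, kind), invisibly.
#' @export
swat_report <- function(result, dir, method = NULL, timestamps = TRUE) {
  stopifnot(inherits(result, "swat_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  config <- result$config
  method <- method %||% names(result$methods)[1]
  mm <- result$methods[[method]]
  ts <- if (timestamps) format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z") else NULL
  w <- config$report_window
  manifest <- list()
  add <- function(file, kind) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(file = file, kind = kind)
  }

  tab_paths <- write_region_tables(mm$regions, dir)
  for (p in tab_paths) add(basename(p), "table")
  if (nrow(mm$priority)) {
    pri <- mm$priority
    pri$start <- pri$start + 1L
    readr::write_tsv(pri, file.path(dir, "prioritized_mri.tsv"), progress = FALSE)
    add("prioritized_mri.tsv", "table")
  }

  cri <- mm$regions$cri
  cri_w <- if (nrow(cri)) cri[cri$w == w, ] else cri
  mri <- mm$regions$mri
  mri_w <- if (nrow(mri)) mri[mri$w == w, ] else mri

  # region pages
  if (nrow(cri_w)) {
    for (i in seq_len(nrow(cri_w))) {
      mr <- mri_w[mri_w$chrom == cri_w$chrom[i] &
                    mri_w$direction == cri_w$direction[i] &
                    mri_w$cri == cri_w$cri[i], ]
      fn <- region_page(cri_w[i, ], mr, mm$calls, dir,
                        build = config$genome_build, timestamp = ts)
      add(fn, "region_page")
    }
  }

  # per-chromosome pages + figures
  chroms <- unique(result$probes$chrom)
  for (ch in chroms) {
    fig <- sprintf("overview_chr%s.png", ch)
    ov <- plot_chromosome_overview(result$probes, mm$tracks, mm$regions,
                                   mm$calls, ch, config)
    save_figure(ov, file.path(dir, fig))
    add(fig, "figure")
    ctab <- cri_w[cri_w$chrom == ch, , drop = FALSE]
    if (nrow(ctab)) {
      ctab <- ctab[order(ctab$start), ]
      link <- sprintf("<a href='%s'>%s_CRI_%d</a>",
                      region_page_name(ctab$direction, ctab$chrom, ctab$cri),
                      ctab$direction, ctab$cri)
      show <- tibble::tibble(
        region = link, direction = ctab$direction,
        probes = sprintf("%d-%d", ctab$probe_first, ctab$probe_last),
        span = sprintf("%s:%d-%d", ctab$chrom, ctab$start + 1L, ctab$end),
        AT = ctab$at, peak_pws = ctab$peak_pws)
    } else show <- tibble::tibble()
    body <- paste0(
      sprintf("<img src='%s' width='760'>\n", fig),
      sprintf("<h2>CRIs at %d-probe windows</h2>\n", w),
      html_table(show),
      "<p><a href='index.html'>back to index</a></p>")
    fn <- sprintf("chr%s.html", ch)
    writeLines(html_page(sprintf("Chromosome %s (%s)", ch, method),
                         body, ts), file.path(dir, fn))
    add(fn, "chromosome_page")
  }

  # karyogram
  kfig <- "karyogram.png"
  save_figure(plot_karyogram(mm$regions, result$probes, mm$calls,
                             mm$priority, config),
              file.path(dir, kfig), width = 7, height = 8)
  add(kfig, "figure")

  # clustering + heatmap
  cluster_body <- "<p>(no clustering performed)</p>"
  if (!is.null(result$clusters)) {
    grp <- tibble::tibble(sample = names(result$clusters$groups),
                          group = unname(result$clusters$groups))
    readr::write_tsv(grp, file.path(dir, "cluster_groups.tsv"), progress = FALSE)
    add("cluster_groups.tsv", "table")
    cluster_body <- html_table(grp)
  }
  if (!is.null(result$heatmap)) {
    readr::write_tsv(result$heatmap, file.path(dir, "region_heatmap.tsv"),
                     progress = FALSE)
    add("region_heatmap.tsv", "table")
    hfig <- "region_heatmap.png"
    save_figure(plot_region_heatmap(result$heatmap,
                                    result$clusters$groups),
                file.path(dir, hfig))
    add(hfig, "figure")
    cluster_body <- paste0(cluster_body,
                           sprintf("\n<img src='%s' width='700'>", hfig))
  }

  # consensus table
  cons_body <- ""
  if (!is.null(result$consensus) && !is.null(result$consensus$final)) {
    fin <- result$consensus$final
    readr::write_tsv(fin, file.path(dir, "consensus_regions.tsv"),
                     progress = FALSE)
    add("consensus_regions.tsv", "table")
    show <- dplyr::mutate(fin, span = sprintf("%s:%d-%d", .data$chrom,
                                              .data$start + 1L, .data$end))
    cons_body <- paste0("<h2>Consensus regions (both prioritisations, >= ",
                        config$consensus_min_methods, " methods)</h2>\n",
                        html_table(show[, c("span", "direction", "n_methods",
                                            "methods")]))
  }

  # genome-ordered CRI index table
  if (nrow(cri_w)) {
    g <- cri_w[order(chrom_factor(cri_w$chrom), cri_w$start), ]
    gl <- sprintf("<a href='%s'>%s_CRI_%d</a>",
                  region_page_name(g$direction, g$chrom, g$cri),
                  g$direction, g$cri)
    gt <- tibble::tibble(
      row = seq_len(nrow(g)), region = gl, chrom = g$chrom,
      direction = g$direction,
      span = sprintf("%d-%d", g$start + 1L, g$end),
      AT = g$at, peak_pws = g$peak_pws)
  } else gt <- tibble::tibble()
  chrom_links <- paste(sprintf("<a href='chr%s.html'>chr%s</a>", chroms,
                               chroms), collapse = " | ")
  body <- paste0(
    sprintf("<p>Method: <b>%s</b>; %d samples; window size %d for tables.</p>\n",
            method, length(sample_ids(result$probes)), w),
    "<p>", chrom_links, "</p>\n",
    sprintf("<p><img src='%s' width='520'></p>\n", kfig),
    "<h2>All CRIs in genome order</h2>\n", html_table(gt), "\n",
    cons_body,
    "<h2>Sample clustering</h2>\n", cluster_body)
  writeLines(html_page("CNA regions of interest", body, ts),
             file.path(dir, "index.html"))
  add("index.html", "index")

  man <- dplyr::bind_rows(manifest)
  readr::write_tsv(man, file.path(dir, "manifest.tsv"), progress = FALSE)
  invisible(man)
}
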
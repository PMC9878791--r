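#' Styling for the publication plots
#'
#' @param colors Named vector mapping variables / groups / classes to colors;
#'   entities without an entry fall back to a deterministic palette.
#' @param width,height Figure size in inches.
#' @param font_scale Multiplier on base font size.
#' @param formats Image formats to emit, subset of `c("png", "svg")`.
#' @return An object of class `pd_style`.
#' @export
style_spec <- function(colors = character(0), width = 7, height = 5,
                       font_scale = 1, formats = c("png", "svg")) {
  structure(list(colors = colors, width = width, height = height,
                 font_scale = font_scale, formats = formats),
            class = "pd_style")
}

pd_palette <- function(keys, colors = character(0)) {
  base <- grDevices::hcl.colors(max(3L, length(keys)), "Dark 3")[seq_along(keys)]
  out <- stats::setNames(base, keys)
  hit <- intersect(keys, names(colors))
  out[hit] <- colors[hit]
  out
}

write_tsv_twin <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

save_plot <- function(p, stem, style) {
  files <- character(0)
  if ("png" %in% style$formats) {
    f <- paste0(stem, ".png")
    dev <- if (requireNamespace("ragg", quietly = TRUE)) ragg::agg_png else grDevices::png
    ok <- tryCatch({
      ggplot2::ggsave(f, p, device = dev, width = style$width,
                      height = style$height, dpi = 300, units = "in")
      TRUE
    }, error = function(e) FALSE)
    if (ok) files <- c(files, f)
  }
  if ("svg" %in% style$formats && capabilities("cairo")) {
    f <- paste0(stem, ".svg")
    ok <- tryCatch({
      ggplot2::ggsave(f, p, device = grDevices::svg, width = style$width,
                      height = style$height)
      TRUE
    }, error = function(e) FALSE)
    if (ok) files <- c(files, f)
  }
  files
}

#' Stratum-mean table behind the parallel coordinates plot
#'
#' One line per dependent-level x conditioning stratum across the
#' quantitative variables; values are stratum means, on the original scale or
#' standardized (mean 0 / SD 1 across individuals) when `scaled = TRUE`.
#' Pairwise-genotype subsets (e.g. WT vs Homo only) are supported through
#' `subset`.
#'
#' @param summaries A [group_summaries()] table (original scale).
#' @param scaled Standardize the means using `scaling`?
#' @param scaling The `$scaling` element of a scaled [pheno_table] (required
#'   when `scaled = TRUE`).
#' @param subset Optional character vector of dependent-variable levels to
#'   keep (matched against the first `:`-field of the stratum key).
#' @return data.frame: stratum, variable, mean, lower, upper.
#' @export
parallel_plot_data <- function(summaries, scaled = FALSE, scaling = NULL,
                               subset = NULL) {
  out <- summaries[, c("stratum", "variable", "mean", "lower", "upper")]
  if (scaled) {
    if (is.null(scaling)) stop("pd_bad_threshold: scaled = TRUE needs the scaling constants")
    ctr <- scaling$center[out$variable]
    scl <- scaling$scale[out$variable]
    out$mean <- (out$mean - ctr) / scl
    out$lower <- (out$lower - ctr) / scl
    out$upper <- (out$upper - ctr) / scl
  }
  if (!is.null(subset)) {
    dep_level <- vapply(strsplit(out$stratum, ":", fixed = TRUE), `[[`, "", 1L)
    out <- out[dep_level %in% subset, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# minimal self-contained interactive 3D scatter (drag to rotate)
write_html_3d <- function(df, path, title) {
  pts <- jsonlite::toJSON(df, dataframe = "rows", digits = 6)
  html <- paste0(
    "<!DOCTYPE html><html><head><meta charset='utf-8'><title>", title,
    "</title></head><body><h3>", title,
    "</h3><p>Drag to rotate.</p><canvas id='c' width='700' height='600'></canvas>",
    "<script>\nvar pts=", pts, ";\n",
    "var ax=0.5,ay=0.5,cv=document.getElementById('c'),ctx=cv.getContext('2d');\n",
    "var cols={};var pal=['#1b9e77','#d95f02','#7570b3','#e7298a','#66a61e','#e6ab02'];var ci=0;\n",
    "function col(g){if(!(g in cols)){cols[g]=pal[ci++%pal.length];}return cols[g];}\n",
    "function draw(){ctx.clearRect(0,0,700,600);\n",
    " var ca=Math.cos(ax),sa=Math.sin(ax),cb=Math.cos(ay),sb=Math.sin(ay);\n",
    " pts.forEach(function(p){\n",
    "  var x=p.dim1,y=p.dim2,z=p.dim3||0;\n",
    "  var x1=x*cb+z*sb, z1=-x*sb+z*cb;\n",
    "  var y1=y*ca-z1*sa, z2=y*sa+z1*ca;\n",
    "  var s=40, px=350+s*x1, py=300-s*y1, r=Math.max(2,4+z2*0.5);\n",
    "  ctx.fillStyle=col(p.group);ctx.beginPath();ctx.arc(px,py,r,0,7);ctx.fill();});\n",
    " var k=0;for(var g in cols){ctx.fillStyle=cols[g];ctx.fillRect(10,10+18*k,12,12);\n",
    "  ctx.fillStyle='#000';ctx.fillText(g,28,20+18*k);k++;}}\n",
    "var drag=false,lx,ly;cv.onmousedown=function(e){drag=true;lx=e.clientX;ly=e.clientY;};\n",
    "window.onmouseup=function(){drag=false;};\n",
    "window.onmousemove=function(e){if(!drag)return;ay+=(e.clientX-lx)*0.01;ax+=(e.clientY-ly)*0.01;lx=e.clientX;ly=e.clientY;draw();};\n",
    "draw();</script></body></html>")
  writeLines(html, path)
  path
}

#' Render the nine publication outputs of one analysis model
#'
#' Writes, into folders named exactly as the pipeline's output convention
#' (`partialAxes_Plot1`, `groupContribution_Plot2`,
#' `individualCoordinates_Plot3`, `sqload_Plot4`,
#' `quantitativeVarCoordinates_Plot5`, `levelsComponents_Plot6`,
#' `paralelPlot` (sic — kept verbatim for drop-in compatibility),
#' `importance_variables`, `cumulativeVariance`), one figure plus a
#' machine-readable TSV twin each; the 3D individual-coordinates view is an
#' interactive HTML next to its static 2D projections. A missing upstream
#' result skips its plot with a logged reason; the rest are still produced.
#'
#' @param mfa A [mfamix()] result (or `NULL`).
#' @param selection A [correlation_matrix()]/[remove_correlated()] report
#'   (or `NULL`).
#' @param importances Combined importance table from the `fit_*_importance`
#'   functions (or `NULL`).
#' @param summaries A [group_summaries()] table (or `NULL`).
#' @param style A [style_spec()].
#' @param outdir Output directory.
#' @param scaling Scaling constants for the scaled parallel plot variant.
#' @return Manifest list: `files` (all written paths), `skipped`
#'   (named reasons).
#' @export
render_all <- function(mfa = NULL, selection = NULL, importances = NULL,
                       summaries = NULL, style = style_spec(), outdir = ".",
                       scaling = NULL) {
  manifest <- list(files = character(0), skipped = character(0))
  add <- function(fs) manifest$files <<- c(manifest$files, fs)
  skip <- function(what, why) manifest$skipped[what] <<- why
  mkdir <- function(d) {
    p <- file.path(outdir, d)
    dir.create(p, showWarnings = FALSE, recursive = TRUE)
    p
  }
  dims_avail <- if (!is.null(mfa)) nrow(mfa$eig) else 0L
  thm <- ggplot2::theme_minimal(base_size = 11 * style$font_scale)

  # 1. partial axes ---------------------------------------------------------
  if (!is.null(mfa) && !is.null(mfa$partial_axes) && dims_avail >= 2L) {
    d <- mkdir("partialAxes_Plot1")
    pa <- do.call(rbind, lapply(names(mfa$partial_axes), function(g) {
      m <- mfa$partial_axes[[g]]
      data.frame(group = g, axis = rownames(m),
                 dim1 = m[, 1], dim2 = m[, 2],
                 dim3 = if (ncol(m) >= 3) m[, 3] else NA_real_,
                 row.names = NULL)
    }))
    add(write_tsv_twin(pa, file.path(d, "partial_axes.tsv")))
    p <- ggplot2::ggplot(pa, ggplot2::aes(x = dim1, y = dim2, color = group)) +
      ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = 0)) +
      ggplot2::geom_point() +
      ggplot2::scale_color_manual(values = pd_palette(unique(pa$group), style$colors)) +
      ggplot2::coord_equal(xlim = c(-1, 1), ylim = c(-1, 1)) + thm +
      ggplot2::labs(title = "Partial axes: group dimensions vs global dimensions")
    add(save_plot(p, file.path(d, "partial_axes"), style))
  } else skip("partialAxes_Plot1", "no MFA result with >= 2 dimensions")

  # 2. group contributions --------------------------------------------------
  if (!is.null(mfa) && !is.null(mfa$group_contrib)) {
    d <- mkdir("groupContribution_Plot2")
    gc_ <- mfa$group_contrib[, seq_len(min(3L, dims_avail)), drop = FALSE]
    df <- data.frame(group = rep(rownames(gc_), ncol(gc_)),
                     dim = rep(colnames(gc_), each = nrow(gc_)),
                     contribution = as.vector(gc_))
    add(write_tsv_twin(df, file.path(d, "group_contributions.tsv")))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = group, y = contribution, fill = group)) +
      ggplot2::geom_col() + ggplot2::facet_wrap(~dim) +
      ggplot2::scale_fill_manual(values = pd_palette(unique(df$group), style$colors)) +
      thm + ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
      ggplot2::labs(title = "Group contributions to the leading dimensions")
    add(save_plot(p, file.path(d, "group_contributions"), style))
  } else skip("groupContribution_Plot2", "no MFA group contributions")

  # 3. individual coordinates (2D + 3D) ------------------------------------
  if (!is.null(mfa) && dims_avail >= 2L) {
    d <- mkdir("individualCoordinates_Plot3")
    sc <- as.data.frame(mfa$scores[, seq_len(min(3L, dims_avail)), drop = FALSE])
    sc$group <- attr(mfa, "individual_groups") %||% "all"
    add(write_tsv_twin(sc, file.path(d, "individual_coordinates.tsv")))
    for (pair in list(c(1, 2), if (dims_avail >= 3) c(1, 3), if (dims_avail >= 3) c(2, 3))) {
      if (is.null(pair)) next
      xv <- paste0("dim", pair[1]); yv <- paste0("dim", pair[2])
      p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data[[xv]], y = .data[[yv]],
                                            color = group)) +
        ggplot2::geom_point(alpha = 0.8) +
        ggplot2::scale_color_manual(values = pd_palette(unique(sc$group), style$colors)) +
        thm + ggplot2::labs(title = sprintf("Individuals: %s vs %s", xv, yv))
      add(save_plot(p, file.path(d, paste0("individuals_", xv, "_", yv)), style))
    }
    if (dims_avail >= 3L) {
      add(write_html_3d(sc, file.path(d, "individuals_3d.html"),
                        "Individual coordinates (dims 1-3)"))
    }
  } else skip("individualCoordinates_Plot3", "no MFA result with >= 2 dimensions")

  # 4. squared loadings -----------------------------------------------------
  if (!is.null(mfa)) {
    d <- mkdir("sqload_Plot4")
    sl <- mfa$sqload[, seq_len(min(3L, dims_avail)), drop = FALSE]
    df <- data.frame(variable = rownames(sl), sl, row.names = NULL,
                     check.names = FALSE)
    add(write_tsv_twin(df, file.path(d, "squared_loadings.tsv")))
    if (dims_avail >= 2L) {
      p <- ggplot2::ggplot(df, ggplot2::aes(x = dim1, y = dim2, label = variable)) +
        ggplot2::geom_point() + ggplot2::geom_text(vjust = -0.6, size = 3 * style$font_scale) +
        thm + ggplot2::labs(title = "Squared loadings (dim 1 vs dim 2)")
      add(save_plot(p, file.path(d, "squared_loadings"), style))
    }
  } else skip("sqload_Plot4", "no factor result")

  # 5. quantitative variable correlations ----------------------------------
  if (!is.null(mfa) && !is.null(mfa$quant_cor) && dims_avail >= 2L) {
    d <- mkdir("quantitativeVarCoordinates_Plot5")
    qc <- mfa$quant_cor[, seq_len(min(3L, dims_avail)), drop = FALSE]
    df <- data.frame(variable = rownames(qc), qc, row.names = NULL,
                     check.names = FALSE)
    add(write_tsv_twin(df, file.path(d, "quantitative_correlations.tsv")))
    circ <- data.frame(t = seq(0, 2 * pi, length.out = 200))
    p <- ggplot2::ggplot(df) +
      ggplot2::geom_path(data = circ, ggplot2::aes(x = cos(t), y = sin(t)),
                         color = "grey70") +
      ggplot2::geom_segment(ggplot2::aes(x = 0, y = 0, xend = dim1, yend = dim2),
                            arrow = grid::arrow(length = grid::unit(2, "mm"))) +
      ggplot2::geom_text(ggplot2::aes(x = dim1, y = dim2, label = variable),
                         vjust = -0.6, size = 3 * style$font_scale) +
      ggplot2::coord_equal() + thm +
      ggplot2::labs(title = "Correlation circle (dims 1-2)")
    add(save_plot(p, file.path(d, "correlation_circle"), style))
  } else skip("quantitativeVarCoordinates_Plot5", "no quantitative correlations")

  # 6. qualitative level coordinates ----------------------------------------
  if (!is.null(mfa) && !is.null(mfa$level_coord) && dims_avail >= 2L) {
    d <- mkdir("levelsComponents_Plot6")
    lc <- mfa$level_coord[, seq_len(min(3L, dims_avail)), drop = FALSE]
    df <- data.frame(level = rownames(lc), lc, row.names = NULL,
                     check.names = FALSE)
    add(write_tsv_twin(df, file.path(d, "level_coordinates.tsv")))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = dim1, y = dim2, label = level)) +
      ggplot2::geom_point(color = "#7570b3") +
      ggplot2::geom_text(vjust = -0.6, size = 3 * style$font_scale) + thm +
      ggplot2::labs(title = "Qualitative level coordinates (dims 1-2)")
    add(save_plot(p, file.path(d, "level_coordinates"), style))
  } else skip("levelsComponents_Plot6", "no qualitative levels")

  # 7. parallel coordinates --------------------------------------------------
  if (!is.null(summaries)) {
    d <- mkdir("paralelPlot")
    for (variant in c("raw", if (!is.null(scaling)) "scaled")) {
      pp <- parallel_plot_data(summaries, scaled = identical(variant, "scaled"),
                               scaling = scaling)
      add(write_tsv_twin(pp, file.path(d, paste0("parallel_", variant, ".tsv"))))
      p <- ggplot2::ggplot(pp, ggplot2::aes(x = variable, y = mean,
                                            group = stratum, color = stratum)) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::scale_color_manual(values = pd_palette(unique(pp$stratum), style$colors)) +
        thm + ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
        ggplot2::labs(title = paste("Parallel coordinates of stratum means,", variant))
      add(save_plot(p, file.path(d, paste0("parallel_", variant)), style))
    }
  } else skip("paralelPlot", "no group summaries")

  # 8. importances -----------------------------------------------------------
  if (!is.null(importances) && nrow(importances)) {
    d <- mkdir("importance_variables")
    add(write_tsv_twin(importances, file.path(d, "importances.tsv")))
    p <- ggplot2::ggplot(importances,
                         ggplot2::aes(x = scaled, y = variable, color = classifier)) +
      ggplot2::geom_point(size = 2) + ggplot2::facet_wrap(~class) +
      ggplot2::scale_color_manual(values = pd_palette(unique(importances$classifier),
                                                      style$colors)) +
      thm + ggplot2::labs(title = "Scaled variable importance (max = 100)",
                          x = "scaled importance")
    add(save_plot(p, file.path(d, "importances"), style))
  } else skip("importance_variables", "no classifier importances")

  # 9. cumulative variance ---------------------------------------------------
  if (!is.null(mfa)) {
    d <- mkdir("cumulativeVariance")
    cv <- cumulative_variance(mfa, 10L)
    add(write_tsv_twin(cv, file.path(d, "cumulative_variance.tsv")))
    p <- ggplot2::ggplot(cv, ggplot2::aes(x = dim)) +
      ggplot2::geom_col(ggplot2::aes(y = percentage), fill = "#1b9e77") +
      ggplot2::geom_line(ggplot2::aes(y = cumulative)) +
      ggplot2::geom_point(ggplot2::aes(y = cumulative)) +
      thm + ggplot2::labs(title = "Variance explained by the top dimensions",
                          y = "% of variance")
    add(save_plot(p, file.path(d, "cumulative_variance"), style))
  } else skip("cumulativeVariance", "no factor result")

  manifest
}
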
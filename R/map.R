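# Map builder: combine embedding coordinates, classification labels and
# optional property tables into a renderable document model. The document is
# a plain list of points plus display state; renderers (ggplot2, standalone
# HTML, CSV/JSON exports) are adapters over it, so everything testable lives
# in the model itself.

.neutral_color <- "#BDBDBD"

# deterministic categorical palette: label -> color, fixed by sorted order
.categorical_palette <- function(labels) {
  labs <- sort(unique(labels))
  cols <- grDevices::hcl.colors(max(length(labs), 2L), palette = "Dark 3")[seq_along(labs)]
  stats::setNames(cols, labs)
}

#' Build a structure-function map document
#'
#' Joins embedding coordinates with classification results into a 3D map
#' document: one point per structure, colored by the chosen level of the
#' classification hierarchy. The label-to-color assignment is deterministic
#' (fixed by sorted label order), so identical inputs give identical maps.
#'
#' @param coords Embedding coordinates: a `pfas_tsne` object or a tibble with
#'   `tsne_pca_1..3` (e.g. rows from [place_user_points()] appended).
#' @param classes Classification results from [pfas_classify()].
#' @param level Label level for coloring: `"category"`, `"class"`, or
#'   `"subclass"`. Structures with no label at that level fall back to the
#'   next level up.
#' @return A `pfas_map` document: `points` tibble (id, coordinates, labels,
#'   color, hover text), `level`, `view` ("3d"), `axes`, `color_mode`.
#'   Structures present in only one input are dropped with a warning.
#' @export
pfas_map <- function(coords, classes, level = c("class", "category", "subclass")) {
  level <- match.arg(level)
  if (inherits(coords, "pfas_tsne")) coords <- coords$coordinates
  key <- if ("id" %in% names(coords) && "id" %in% names(classes)) "id" else "canonical_smiles"
  if (!key %in% names(coords) || !key %in% names(classes)) {
    stop("key_mismatch: coords and classes share neither an id nor a canonical_smiles key")
  }
  only_coords <- setdiff(coords[[key]], classes[[key]])
  only_classes <- setdiff(classes[[key]], coords[[key]])
  if (length(only_coords) > 0 || length(only_classes) > 0) {
    warning(
      "key_mismatch: dropping ", length(only_coords), " coordinate row(s) and ",
      length(only_classes), " classification row(s) present in one input only"
    )
  }
  pts <- dplyr::inner_join(coords, classes, by = key, suffix = c("", ".cls"))
  label <- switch(level,
    category = pts$category,
    class = dplyr::coalesce(pts$class, pts$category),
    subclass = dplyr::coalesce(pts$subclass, pts$class, pts$category)
  )
  pal <- .categorical_palette(label)
  id <- if ("id" %in% names(pts)) pts$id else pts[[key]]
  points <- tibble::tibble(
    id = id,
    tsne_pca_1 = pts$tsne_pca_1,
    tsne_pca_2 = pts$tsne_pca_2,
    tsne_pca_3 = pts$tsne_pca_3,
    category = pts$category,
    class = pts$class,
    subclass = pts$subclass,
    label = label,
    color = unname(pal[label]),
    provenance = if ("provenance" %in% names(pts)) pts$provenance else "reference",
    hover = paste0(
      id, " | ", pts$category,
      ifelse(is.na(pts$class), "", paste0(" / ", pts$class)),
      ifelse(is.na(pts$subclass), "", paste0(" / ", pts$subclass)),
      ifelse(is.na(pts$n) | pts$n == 0, "", paste0(" | n=", pts$n))
    )
  )
  structure(
    list(
      points = points, level = level, palette = pal,
      view = "3d", axes = c(1L, 2L, 3L),
      color_mode = "categorical",
      property = NULL
    ),
    class = "pfas_map"
  )
}

#' Overlay a per-compound property on a map
#'
#' Points with a supplied value switch to a continuous color scale (linear
#' between the minimum and maximum supplied values); points without a value
#' are rendered in a neutral gray; hover text is augmented. Coordinates and
#' classification labels are never modified. Ids in the table that are not on
#' the map are tolerated.
#'
#' @param doc A `pfas_map` document.
#' @param table A data frame with columns `id` and `value`, or a named
#'   numeric vector.
#' @param property_name Name of the property (used in hover text and legend).
#' @param diverging Use a blue-to-red diverging scale instead of the default
#'   sequential (viridis) scale.
#' @return The modified `pfas_map` document.
#' @export
overlay_property <- function(doc, table, property_name, diverging = FALSE) {
  stopifnot(inherits(doc, "pfas_map"))
  if (is.numeric(table) && !is.null(names(table))) {
    table <- tibble::tibble(id = names(table), value = unname(table))
  }
  stopifnot(is.data.frame(table), all(c("id", "value") %in% names(table)))
  stopifnot(is.numeric(table$value))
  vals <- stats::setNames(table$value, table$id)[doc$points$id]
  doc$property <- list(
    name = property_name,
    values = unname(vals),
    range = if (any(!is.na(vals))) range(vals, na.rm = TRUE) else c(NA_real_, NA_real_),
    diverging = diverging
  )
  if (any(!is.na(vals))) {
    ramp <- if (diverging) {
      grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(101)
    } else {
      grDevices::hcl.colors(101, palette = "viridis")
    }
    rg <- doc$property$range
    span <- if (diff(rg) > 0) diff(rg) else 1
    idx <- 1L + as.integer(round(100 * (vals - rg[1]) / span))
    doc$points$color <- ifelse(is.na(vals), .neutral_color, ramp[idx])
    doc$points$hover <- ifelse(
      is.na(vals),
      doc$points$hover,
      paste0(doc$points$hover, " | ", property_name, "=", signif(vals, 4))
    )
    doc$color_mode <- "continuous"
  }
  doc$points$property <- unname(vals)
  doc
}

#' Convert a hit-ratio fraction string to a percentage
#'
#' Parses `"a/b"` (non-negative integer a, positive integer b) and returns
#' 100 a / b rounded to one decimal, the form used to annotate chemical
#' activity summaries (e.g. `"210/851"` is 24.7).
#'
#' @param text Character vector of fraction strings.
#' @return Numeric vector of percentages.
#' @examples
#' fraction_to_percent("210/851")
#' @export
fraction_to_percent <- function(text) {
  vapply(as.character(text), function(x) {
    m <- regmatches(x, regexec("^\\s*([0-9]+)\\s*/\\s*([0-9]+)\\s*$", x))[[1]]
    if (length(m) != 3) stop("malformed_fraction: ", x)
    a <- as.numeric(m[2])
    b <- as.numeric(m[3])
    if (b == 0) stop("zero_denominator: ", x)
    round(100 * a / b, 1)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Project a map document onto two of its stored axes
#'
#' The 2D view uses exactly two of the three stored components without
#' recomputation; the third coordinate stays in the document (and in hover
#' text), so re-rendering in 3D restores the original map.
#'
#' @param doc A `pfas_map` document.
#' @param axes Integer pair, a subset of 1:3 (e.g. `c(2, 3)`).
#' @return The document with `view = "2d"` and the axis pair set.
#' @export
project_2d <- function(doc, axes = c(2L, 3L)) {
  stopifnot(inherits(doc, "pfas_map"))
  axes <- as.integer(axes)
  if (length(axes) != 2 || anyNA(axes) || !all(axes %in% 1:3) || axes[1] == axes[2]) {
    stop("invalid_axes: need two distinct axes from 1:3")
  }
  doc$view <- "2d"
  doc$axes <- axes
  doc
}

#' @export
print.pfas_map <- function(x, ...) {
  cat(
    "<pfas_map> ", nrow(x$points), " points, level=", x$level,
    ", view=", x$view,
    if (x$view == "2d") paste0(" (TSNE-PCA-", x$axes[1], "/", x$axes[2], ")") else "",
    ", color=", x$color_mode,
    if (!is.null(x$property)) paste0(" [", x$property$name, "]") else "",
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Point table of a map document
#'
#' @param x A `pfas_map` document.
#' @param ... Unused.
#' @return The `points` tibble.
#' @method tidy pfas_map
#' @export
tidy.pfas_map <- function(x, ...) {
  x$points
}

#' Plot a map document
#'
#' Renders the document's current view with ggplot2: the selected axis pair
#' for 2D projections, the first two stored axes for 3D documents.
#'
#' @param object A `pfas_map` document.
#' @param point_size Marker size.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pfas_map
#' @export
autoplot.pfas_map <- function(object, point_size = 1.5, ...) {
  axes <- if (object$view == "2d") object$axes else object$axes[1:2]
  xcol <- paste0("tsne_pca_", axes[1])
  ycol <- paste0("tsne_pca_", axes[2])
  pts <- object$points
  if (object$color_mode == "continuous") {
    p <- ggplot2::ggplot(pts, ggplot2::aes(
      x = .data[[xcol]], y = .data[[ycol]], color = .data$property
    )) +
      ggplot2::geom_point(size = point_size, na.rm = FALSE) +
      (if (isTRUE(object$property$diverging)) {
        ggplot2::scale_color_gradient2(
          low = "#2166AC", mid = "#F7F7F7", high = "#B2182B",
          midpoint = mean(object$property$range), na.value = .neutral_color,
          name = object$property$name
        )
      } else {
        ggplot2::scale_color_viridis_c(
          na.value = .neutral_color, name = object$property$name
        )
      })
  } else {
    p <- ggplot2::ggplot(pts, ggplot2::aes(
      x = .data[[xcol]], y = .data[[ycol]], color = .data$label
    )) +
      ggplot2::geom_point(size = point_size) +
      ggplot2::scale_color_manual(values = object$palette, name = object$level)
  }
  p +
    ggplot2::labs(
      x = paste0("TSNE-PCA-", axes[1]),
      y = paste0("TSNE-PCA-", axes[2])
    ) +
    ggplot2::theme_minimal()
}

# document model as a plain list (JSON-ready)
.map_document_model <- function(doc) {
  list(
    level = doc$level,
    view = doc$view,
    axes = doc$axes,
    color_mode = doc$color_mode,
    property = if (is.null(doc$property)) NULL else doc$property[c("name", "range", "diverging")],
    palette = as.list(doc$palette),
    points = as.list(doc$points)  # column-wise arrays
  )
}

#' Export a map document
#'
#' `write_map_csv()` writes the point table; `write_map_json()` the full
#' document model; `write_map_html()` a self-contained interactive page (the
#' document model embedded as JSON plus a small canvas renderer with drag
#' rotation and hover labels).
#'
#' @param doc A `pfas_map` document.
#' @param path Output file path.
#' @param title Page title for the HTML export.
#' @return `doc`, invisibly.
#' @export
write_map_csv <- function(doc, path) {
  utils::write.csv(doc$points, path, row.names = FALSE)
  invisible(doc)
}

#' @rdname write_map_csv
#' @export
write_map_json <- function(doc, path) {
  jsonlite::write_json(.map_document_model(doc), path,
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(doc)
}

#' @rdname write_map_csv
#' @export
write_map_html <- function(doc, path, title = "PFAS structure-function map") {
  model <- jsonlite::toJSON(.map_document_model(doc),
    auto_unbox = TRUE, digits = NA, null = "null")
  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"><title>", title,
    "</title>\n<style>body{font-family:sans-serif;margin:12px}#c{border:1px solid #ccc}",
    "#hover{height:1.2em;color:#333}</style></head>\n<body>\n<h3>", title, "</h3>\n",
    "<div id=\"hover\">&nbsp;</div>\n<canvas id=\"c\" width=\"820\" height=\"620\"></canvas>\n",
    "<script>\nvar MODEL = ", model, ";\n", .map_html_js, "</script>\n</body></html>\n"
  )
  writeLines(html, path)
  invisible(doc)
}

# Minimal canvas renderer: orthographic projection of the stored coordinates
# with mouse-drag rotation (3D view) or the fixed axis pair (2D view).
.map_html_js <- "
var cv=document.getElementById('c'),cx=cv.getContext('2d');
var P=MODEL.points, ax=MODEL.axes, is2d=(MODEL.view==='2d');
var xs=[],ys=[],zs=[];
for(var i=0;i<P.id.length;i++){xs.push(P['tsne_pca_'+(is2d?ax[0]:1)][i]);
 ys.push(P['tsne_pca_'+(is2d?ax[1]:2)][i]);zs.push(is2d?0:P.tsne_pca_3[i]);}
var mn=Math.min,mx=Math.max;
var lo=[mn.apply(0,xs),mn.apply(0,ys),mn.apply(0,zs)],hi=[mx.apply(0,xs),mx.apply(0,ys),mx.apply(0,zs)];
var span=mx(hi[0]-lo[0],mx(hi[1]-lo[1],hi[2]-lo[2]))||1;
var a=0.5,b=0.3,drag=false,px=0,py=0;
function draw(){cx.clearRect(0,0,cv.width,cv.height);
 var ca=Math.cos(a),sa=Math.sin(a),cb=Math.cos(b),sb=Math.sin(b);
 for(var i=0;i<xs.length;i++){
  var x=(xs[i]-(lo[0]+hi[0])/2)/span,y=(ys[i]-(lo[1]+hi[1])/2)/span,z=(zs[i]-(lo[2]+hi[2])/2)/span;
  var u=x*ca+z*sa,w=-x*sa+z*ca,v=y*cb-w*sb;
  var sx=410+u*560,sy=310-v*560;
  cx.fillStyle=P.color[i];cx.beginPath();cx.arc(sx,sy,3,0,6.284);cx.fill();
  P._sx=P._sx||[];P._sy=P._sy||[];P._sx[i]=sx;P._sy[i]=sy;}}
cv.onmousedown=function(e){drag=true;px=e.offsetX;py=e.offsetY;};
window.onmouseup=function(){drag=false;};
cv.onmousemove=function(e){
 if(drag&&!is2d){a+=(e.offsetX-px)*0.01;b+=(e.offsetY-py)*0.01;px=e.offsetX;py=e.offsetY;draw();return;}
 var best=-1,bd=64;
 for(var i=0;i<xs.length;i++){var dx=e.offsetX-P._sx[i],dy=e.offsetY-P._sy[i],d=dx*dx+dy*dy;
  if(d<bd){bd=d;best=i;}}
 document.getElementById('hover').textContent=best>=0?P.hover[best]:'\\u00a0';};
draw();
"
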
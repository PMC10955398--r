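#' Fit a smooth space-time humidity field to a climate grid
#'
#' Interpolates a gridded (year, lat, lon, humidity) table with a
#' tensor-product spline smooth over all three axes
#' (`mgcv::gam(humidity ~ te(year, lat, lon))`), giving a smooth
#' interpolator for humidity at arbitrary points in time and space inside
#' the training bounding box.  Reports in-sample R-squared and k-fold
#' held-out R-squared (fixed fold seed, so the diagnostic is reproducible).
#'
#' @param grid_table data frame with numeric columns `year`, `lat`, `lon`,
#'   `humidity`; at least 2 distinct values per axis.
#' @param k basis dimensions per axis for the tensor product (capped at the
#'   number of unique values per axis).
#' @param folds number of cross-validation folds.
#' @param cv_seed fold-assignment seed.
#' @return an object of class `humidity_field` with elements `model`,
#'   `bbox`, `rsq`, `rsq_cv`, `type`.
#' @export
fit_humidity_field <- function(grid_table, k = c(5, 5, 5), folds = 5,
                               cv_seed = 1L) {
  check_grid(grid_table)
  ku <- vapply(grid_table[c("year", "lat", "lon")],
               function(v) length(unique(v)), integer(1))
  if (any(ku < 2)) stop("degenerate grid: need >= 2 distinct values per axis")
  if (stats::sd(grid_table$humidity) == 0)  # constant response: REML degenerates
    return(structure(list(model = NULL, constant = grid_table$humidity[1],
                          bbox = grid_bbox(grid_table), rsq = 1, rsq_cv = 1,
                          type = "constant"),
                     class = "humidity_field"))
  k <- pmin(k, ku)
  fit_one <- function(dat) {
    mgcv::gam(humidity ~ te(year, lat, lon, k = k), data = dat,
              method = "REML")
  }
  model <- fit_one(grid_table)
  y <- grid_table$humidity
  sst <- sum((y - mean(y))^2)
  rsq <- if (sst > 0) 1 - sum((y - stats::fitted(model))^2) / sst else 1

  n <- nrow(grid_table)
  folds <- min(folds, n)
  fold_id <- with_seed(cv_seed, sample(rep_len(seq_len(folds), n)))
  pred <- rep(NA_real_, n)
  for (f in seq_len(folds)) {
    tr <- grid_table[fold_id != f, , drop = FALSE]
    ku_tr <- vapply(tr[c("year", "lat", "lon")],
                    function(v) length(unique(v)), integer(1))
    m <- mgcv::gam(humidity ~ te(year, lat, lon, k = pmin(k, ku_tr)),
                   data = tr, method = "REML")
    pred[fold_id == f] <- stats::predict(m, grid_table[fold_id == f, ])
  }
  rsq_cv <- if (sst > 0) 1 - sum((y - pred)^2) / sst else 1

  structure(list(model = model, bbox = grid_bbox(grid_table),
                 rsq = rsq, rsq_cv = rsq_cv, type = "gam"),
            class = "humidity_field")
}

#' Trilinear interpolation baseline on a climate grid
#'
#' Piecewise-(tri)linear interpolation on the full regular
#' (year, lat, lon) grid: the value at a query point is the trilinear blend
#' of the 8 surrounding grid corners.  Exact at grid points and exact for
#' fields linear in all three coordinates; serves as the comparison
#' baseline for the spline interpolator.
#'
#' @param grid_table data frame with columns `year`, `lat`, `lon`,
#'   `humidity` covering the complete crossing of the axis values.
#' @return an object of class `humidity_field` (`type = "trilinear"`).
#' @export
bilinear_baseline <- function(grid_table) {
  check_grid(grid_table)
  ax <- lapply(grid_table[c("year", "lat", "lon")],
               function(v) sort(unique(v)))
  if (nrow(grid_table) != prod(lengths(ax)))
    stop("grid is not a complete crossing of its axis values")
  arr <- array(NA_real_, dim = lengths(ax))
  idx <- cbind(match(grid_table$year, ax$year),
               match(grid_table$lat, ax$lat),
               match(grid_table$lon, ax$lon))
  arr[idx] <- grid_table$humidity
  structure(list(axes = ax, values = arr, bbox = grid_bbox(grid_table),
                 rsq = 1, rsq_cv = NA_real_, type = "trilinear"),
            class = "humidity_field")
}

check_grid <- function(grid_table) {
  req <- c("year", "lat", "lon", "humidity")
  if (!all(req %in% names(grid_table)))
    stop("grid table must have columns: ", paste(req, collapse = ", "))
  if (any(!vapply(grid_table[req], is.numeric, logical(1))))
    stop("grid columns must be numeric")
  invisible(TRUE)
}

grid_bbox <- function(grid_table) {
  list(year = range(grid_table$year), lat = range(grid_table$lat),
       lon = range(grid_table$lon))
}

#' @export
print.humidity_field <- function(x, ...) {
  cat("humidity_field (", x$type, ")\n", sep = "")
  cat("  bbox: year [", paste(format(x$bbox$year), collapse = ", "),
      "], lat [", paste(format(x$bbox$lat), collapse = ", "),
      "], lon [", paste(format(x$bbox$lon), collapse = ", "), "]\n", sep = "")
  cat("  in-sample R^2:", format(x$rsq, digits = 4),
      " held-out R^2:", format(x$rsq_cv, digits = 4), "\n")
  invisible(x)
}

#' Evaluate a humidity field
#'
#' @param object a `humidity_field`.
#' @param newdata data frame with columns `year`, `lat`, `lon`; all points
#'   must lie inside the training bounding box.
#' @param ... unused.
#' @return numeric vector of humidity values.
#' @export
predict.humidity_field <- function(object, newdata, ...) {
  stopifnot(all(c("year", "lat", "lon") %in% names(newdata)))
  bb <- object$bbox
  tol <- 1e-9
  out_of_box <- newdata$year < bb$year[1] - tol | newdata$year > bb$year[2] + tol |
    newdata$lat < bb$lat[1] - tol | newdata$lat > bb$lat[2] + tol |
    newdata$lon < bb$lon[1] - tol | newdata$lon > bb$lon[2] + tol
  if (any(out_of_box))
    stop("query point(s) outside field bounding box: rows ",
         paste(which(out_of_box), collapse = ", "))
  if (object$type == "constant")
    return(rep(object$constant, nrow(newdata)))
  if (object$type == "gam")
    return(as.numeric(stats::predict(object$model, newdata)))
  trilinear_eval(object, newdata)
}

trilinear_eval <- function(field, newdata) {
  ax <- field$axes; arr <- field$values
  one_axis <- function(vals, q) {
    n <- length(vals)
    if (n == 1) return(list(i0 = rep(1, length(q)), i1 = rep(1, length(q)),
                            w = rep(0, length(q))))
    i0 <- findInterval(q, vals, rightmost.closed = TRUE)
    i0 <- pmin(pmax(i0, 1), n - 1)
    i1 <- i0 + 1
    w <- (q - vals[i0]) / (vals[i1] - vals[i0])
    list(i0 = i0, i1 = i1, w = pmin(pmax(w, 0), 1))
  }
  aY <- one_axis(ax$year, newdata$year)
  aL <- one_axis(ax$lat, newdata$lat)
  aO <- one_axis(ax$lon, newdata$lon)
  out <- numeric(nrow(newdata))
  for (dy in 0:1) for (dl in 0:1) for (do in 0:1) {
    iy <- if (dy == 0) aY$i0 else aY$i1
    il <- if (dl == 0) aL$i0 else aL$i1
    io <- if (do == 0) aO$i0 else aO$i1
    wy <- if (dy == 0) 1 - aY$w else aY$w
    wl <- if (dl == 0) 1 - aL$w else aL$w
    wo <- if (do == 0) 1 - aO$w else aO$w
    out <- out + wy * wl * wo * arr[cbind(iy, il, io)]
  }
  out
}

#' Humidity at every node of a geo-phylogeny
#'
#' Converts node ages (ky BP on the tree's reference year) to the climate
#' grid's time axis and evaluates the field at each node's location.  The
#' tree and the climate grid may use different reference years (for the
#' Bantu system: 2000 CE for the tree, 1850 CE for the climate grid).
#'
#' @param field a `humidity_field`.
#' @param tree a [geophylo] object.
#' @param ref_year_tree calendar year (CE) corresponding to age 0 on the
#'   tree.
#' @param ref_year_climate calendar year (CE) corresponding to the climate
#'   grid's zero point (only used when `year_unit = "BP"`).
#' @param year_unit `"CE"` if the grid's `year` column is in calendar years
#'   CE; `"BP"` if it counts years before `ref_year_climate`.
#' @return named numeric vector of humidity values, one per node id.
#' @export
humidity_at_nodes <- function(field, tree, ref_year_tree = 2000,
                              ref_year_climate = 1850,
                              year_unit = c("CE", "BP")) {
  year_unit <- match.arg(year_unit)
  nd <- tree$nodes
  year_ce <- ref_year_tree - 1000 * nd$age
  qyear <- if (year_unit == "CE") year_ce else ref_year_climate - year_ce
  q <- data.frame(year = qyear, lat = nd$lat, lon = nd$lon)
  h <- tryCatch(predict(field, q), error = function(e)
    stop("node(s) outside field bounding box: ",
         conditionMessage(e), call. = FALSE))
  stats::setNames(h, nd$id)
}
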
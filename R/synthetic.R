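## Seeded synthetic crystallization-well renderer. Realism is secondary to
## controllable statistical structure: each outcome class excites distinct
## filter-bank channels (strong straight edges for crystals, mid-scale
## granularity for precipitates, smooth gradients for clear drops), and
## every image ships with ground-truth droplet and crystal masks.

fixtureClasses <- c("clear", "precipitate", "microcrystal_shower",
                    "crystal", "phase_separation", "fault_empty",
                    "fault_small", "fault_offframe")

#' Specify a synthetic droplet fixture
#'
#' Bundles the outcome class, geometry, texture parameters and RNG seed
#' of one synthetic well image. The same spec always renders the same
#' image, bit for bit.
#'
#' @param class one of \code{"clear"}, \code{"precipitate"},
#'   \code{"microcrystal_shower"}, \code{"crystal"},
#'   \code{"phase_separation"}, \code{"fault_empty"},
#'   \code{"fault_small"}, \code{"fault_offframe"}.
#' @param seed RNG seed for this fixture.
#' @param size image side length in pixels (default 384).
#' @param subwell subwell position (\code{"a"}, \code{"b"} or \code{"c"});
#'   controls the frame inset of the plate layout.
#' @param center optional droplet centre (row, col); default near the well
#'   centre with seeded jitter.
#' @param radius optional droplet radius in pixels; default drawn from the
#'   class-typical range.
#' @param texture named list of class texture parameters; recognised
#'   entries include \code{grain} (precipitate noise sd, default 20),
#'   \code{darkMass} (logical: add a central very dark precipitate blob
#'   that defeats plain gradient segmentation, default FALSE),
#'   \code{nCrystals}, \code{nSpecks}.
#' @return an object of class \code{FixtureSpec} (a list).
#' @seealso [generateWell()], [generatePlate()]
#' @export
fixtureSpec <- function(class, seed, size = 384L, subwell = "a",
                        center = NULL, radius = NULL, texture = list()) {
  class <- match.arg(class, fixtureClasses)
  structure(list(class = class, seed = seed, size = as.integer(size),
                 subwell = subwell, center = center, radius = radius,
                 texture = texture),
            class = "FixtureSpec")
}

frameInset <- function(subwell) {
  c(a = 12L, b = 16L, c = 20L)[[subwell]]
}

## distance of every pixel to the image border
borderDistance <- function(n, m) {
  rr <- matrix(seq_len(n), n, m)
  cc <- matrix(seq_len(m), n, m, byrow = TRUE)
  pmin(rr - 1L, n - rr, cc - 1L, m - cc)
}

## filled rotated-rectangle mask (a needle or plate crystal)
rectangleMask <- function(n, m, cr, cc0, len, wid, angle) {
  rr <- matrix(seq_len(n), n, m) - cr
  cc <- matrix(seq_len(m), n, m, byrow = TRUE) - cc0
  u <- cc * cos(angle) + rr * sin(angle)
  v <- -cc * sin(angle) + rr * cos(angle)
  abs(u) <= len / 2 & abs(v) <= wid / 2
}

#' Render a synthetic well image with ground truth
#'
#' Draws the well frame (dark rectangular band with corner shadows and an
#' illumination gradient), the droplet disk with its class texture and a
#' dark rim shadow, dispensing/imaging faults where the class says so, and
#' Gaussian sensor noise. The droplet mask and (for crystalline classes)
#' the crystal-region mask are returned as ground truth.
#'
#' @param spec a [fixtureSpec()] object (or a class name, for an
#'   all-default spec with the given seed).
#' @param seed used only when \code{spec} is a class name.
#' @return list with \code{image} (numeric matrix, 0-255) and
#'   \code{truth}: a list with \code{class}, \code{dropletMask},
#'   \code{crystalMask}, \code{center}, \code{radius}, \code{shift}
#'   (scene offset), \code{subwell}.
#' @examples
#' w <- generateWell(fixtureSpec("crystal", seed = 7))
#' sum(w$truth$crystalMask) > 0
#' @export
generateWell <- function(spec, seed = NULL) {
  if (is.character(spec)) spec <- fixtureSpec(spec, seed = seed)
  stopifnot(inherits(spec, "FixtureSpec"))
  withr::with_seed(spec$seed, renderWell(spec))
}

renderWell <- function(spec) {
  n <- spec$size; m <- spec$size
  cls <- spec$class
  tex <- spec$texture
  inset <- frameInset(spec$subwell)
  frameWidth <- 12L

  shift <- if (cls == "fault_offframe")
    round(stats::runif(2, 60, 100)) * sample(c(-1, 1), 2, replace = TRUE)
  else if (cls == "fault_empty")
    c(0, 0)          # empty wells are imaged at the nominal position, so
                     # averaged backgrounds keep sharp frame edges
  else
    round(stats::runif(2, -6, 6))

  rr <- matrix(seq_len(n), n, m) - shift[1L]
  cc <- matrix(seq_len(m), n, m, byrow = TRUE) - shift[2L]
  bdist <- pmin(rr - 1L, n - rr, cc - 1L, m - cc)  # to nominal border

  img <- matrix(0, n, m)
  outside <- bdist < inset
  frame <- bdist >= inset & bdist < inset + frameWidth
  interior <- bdist >= inset + frameWidth

  # plate surround with corner shadows, dark frame, lit interior
  ctr <- (n + 1) / 2
  radial <- sqrt((rr - ctr)^2 + (cc - ctr)^2) / (ctr * sqrt(2))
  img[outside] <- 130 - 40 * radial[outside]
  img[frame] <- 45
  grad <- 205 - 12 * (cc / m) - 10 * radial^2
  img[interior] <- grad[interior]

  dropletMask <- matrix(FALSE, n, m)
  crystalMask <- matrix(FALSE, n, m)
  center <- NULL; radius <- NULL

  if (!cls %in% "fault_empty") {
    radius <- if (!is.null(spec$radius)) spec$radius else
      switch(cls,
        fault_small = stats::runif(1, 28, 42),
        stats::runif(1, 105, 140))
    jitter <- if (cls == "crystal" && isTRUE(tex$touchFrame)) 0 else
      stats::runif(2, -15, 15)
    center <- if (!is.null(spec$center)) spec$center else
      c(ctr + shift[1L] + jitter[1L], ctr + shift[2L] + jitter[2L])
    if (isTRUE(tex$touchFrame)) {
      # push the droplet against the inner frame edge
      maxR <- ctr - inset - frameWidth
      center[2L] <- ctr + shift[2L] + (maxR - radius - 2)
    }
    pr <- matrix(seq_len(n), n, m) - center[1L]
    pc <- matrix(seq_len(m), n, m, byrow = TRUE) - center[2L]
    d <- sqrt(pr^2 + pc^2)
    dropletMask <- d <= radius

    # droplet interior: slightly darker than the well, mild lens shine
    body <- grad - 18 + 14 * (1 - (d / radius)^2)
    img[dropletMask] <- body[dropletMask]
    # rim shadow: dark annulus just inside the boundary -> a strong,
    # sharp intensity step exactly at the true radius. Heavily
    # precipitated drops (darkMass) image with much weaker rim contrast.
    rimShadow <- if (!is.null(tex$rimShadow)) tex$rimShadow
      else if (isTRUE(tex$darkMass)) 4 else 55
    rim <- dropletMask & d > radius - 7
    rimDepth <- 62 * (1 - (radius - d[rim]) / 7)
    img[rim] <- img[rim] - rimShadow - 0.3 * rimDepth * (rimShadow / 55)

    inner <- dropletMask & d <= radius - 8
    crystalMaskEnv <- new.env()
    img <- addClassTexture(img, cls, tex, inner, center, radius, d,
                           crystalMaskEnv)
    if (!is.null(crystalMaskEnv$mask)) crystalMask <- crystalMaskEnv$mask
  }

  img <- img + stats::rnorm(n * m, 0, 2.5)
  list(image = clamp(img, 0, 255),
       truth = list(class = cls, dropletMask = dropletMask,
                    crystalMask = crystalMask, center = center,
                    radius = radius, shift = shift,
                    subwell = spec$subwell))
}

## stamp small discs of radius 1 or 2 onto a logical matrix, fast
paintSpecks <- function(mask, pr, pc, rad) {
  n <- nrow(mask); m <- ncol(mask)
  offs <- list(
    `1` = expand.grid(dr = -1:1, dc = -1:1),
    `2` = subset(expand.grid(dr = -2:2, dc = -2:2), dr^2 + dc^2 <= 4))
  for (i in seq_along(pr)) {
    o <- offs[[as.character(rad[i])]]
    r <- pr[i] + o$dr; c <- pc[i] + o$dc
    keep <- r >= 1L & r <= n & c >= 1L & c <= m
    mask[cbind(r[keep], c[keep])] <- TRUE
  }
  mask
}

## texture painters; `inner` is the droplet interior excluding the rim zone
addClassTexture <- function(img, cls, tex, inner, center, radius, d, env) {
  n <- nrow(img); m <- ncol(img)
  if (cls %in% c("precipitate")) {
    grain <- if (!is.null(tex$grain)) tex$grain
      else if (isTRUE(tex$darkMass)) 5 else 20
    noise <- matrix(stats::rnorm(n * m), n, m)
    band <- as.matrix(EBImage::gblur(noise, sigma = 1.2))
    band <- band / stats::sd(band) * grain
    img[inner] <- img[inner] + band[inner]
    if (isTRUE(tex$darkMass)) {
      # large, soft-edged dark precipitate mass: its diffuse edge carries
      # more gradient than the weak rim of such drops, but is flattened
      # by the sigma-10 gamma correction (which tracks wide dark regions)
      # while the sharp rim survives
      br <- stats::runif(1, 48, 60)
      bc <- center + stats::runif(2, -8, 8)
      blob <- 1 * diskMask(n, m, bc[1L], bc[2L], br)
      blob <- as.matrix(EBImage::gblur(blob, sigma = 8))
      img <- img - 150 * blob * inner
    }
  } else if (cls == "microcrystal_shower") {
    nSpecks <- if (is.null(tex$nSpecks)) round(stats::runif(1, 100, 500))
      else tex$nSpecks
    sp <- matrix(FALSE, n, m)
    ok <- which(inner & d <= 0.85 * radius)
    if (length(ok)) {
      pts <- sample(ok, min(nSpecks, length(ok)))
      pr <- ((pts - 1L) %% n) + 1L
      pc <- ((pts - 1L) %/% n) + 1L
      rad <- sample(1:2, length(pts), replace = TRUE)
      sp <- paintSpecks(sp, pr, pc, rad)
      sp <- sp & inner
      img[sp] <- img[sp] + 70
      env$mask <- sp
    }
  } else if (cls == "crystal") {
    nCr <- if (is.null(tex$nCrystals)) sample(1:5, 1) else tex$nCrystals
    cm <- matrix(FALSE, n, m)
    for (i in seq_len(nCr)) {
      needle <- stats::runif(1) < 0.6
      len <- if (needle) stats::runif(1, 40, 90) else stats::runif(1, 30, 60)
      wid <- if (needle) stats::runif(1, 4, 10) else stats::runif(1, 16, 40)
      ang <- stats::runif(1, 0, pi)
      rho <- stats::runif(1, 0, 0.55 * radius)
      phi <- stats::runif(1, 0, 2 * pi)
      rc <- rectangleMask(n, m, center[1L] + rho * sin(phi),
                          center[2L] + rho * cos(phi), len, wid, ang)
      cm <- cm | rc
    }
    cm <- cm & inner
    img[cm] <- img[cm] + 80 + stats::rnorm(sum(cm), 0, 3)
    env$mask <- cm
  } else if (cls == "phase_separation") {
    nB <- sample(3:7, 1)
    blobs <- matrix(0, n, m)
    for (i in seq_len(nB)) {
      br <- stats::runif(1, 8, 25)
      rho <- stats::runif(1, 0, 0.6 * radius)
      phi <- stats::runif(1, 0, 2 * pi)
      blobs <- blobs - 35 * diskMask(n, m, center[1L] + rho * sin(phi),
                                     center[2L] + rho * cos(phi), br)
    }
    blobs <- as.matrix(EBImage::gblur(blobs, sigma = 2))
    img[inner] <- img[inner] + blobs[inner]
  }
  # clear, fault_small, fault_offframe: smooth interior only
  img
}

#' Generate a synthetic plate of well images
#'
#' Renders \code{nWells} wells with three subwells each (the standard
#' sitting-drop layout), drawing each droplet's outcome class from
#' \code{classMix}. Optionally writes PNG images plus manifest and
#' ground-truth CSVs to a directory.
#'
#' @param nWells number of wells (default 96).
#' @param classMix named numeric vector of class probabilities (names from
#'   the fixture class list); default a routine screen mix.
#' @param seed RNG seed; per-image seeds are derived from it.
#' @param plate plate identifier used in the manifest (default
#'   \code{"SYN001"}).
#' @param dir optional output directory for PNGs, \code{manifest.csv} and
#'   \code{truth.csv}.
#' @param size image side length (default 384).
#' @param subwells subwell position names (default \code{c("a","b","c")}).
#' @return list with \code{manifest} (data.frame: \code{id}, \code{plate},
#'   \code{well}, \code{subwell}, \code{class}, and \code{path} when
#'   written), \code{images} (list of matrices) and \code{truths} (list of
#'   truth lists).
#' @export
generatePlate <- function(nWells = 96L,
                          classMix = c(clear = 0.45, precipitate = 0.3,
                                       phase_separation = 0.1,
                                       crystal = 0.05,
                                       microcrystal_shower = 0.05,
                                       fault_empty = 0.05),
                          seed = 1L, plate = "SYN001", dir = NULL,
                          size = 384L, subwells = c("a", "b", "c")) {
  classMix <- classMix / sum(classMix)
  nImg <- nWells * length(subwells)
  draws <- withr::with_seed(seed, list(
    classes = sample(names(classMix), nImg, replace = TRUE,
                     prob = classMix),
    seeds = sample.int(.Machine$integer.max - 1L, nImg)))
  manifest <- data.frame(
    id = sprintf("%s_w%03d%s", plate,
                 rep(seq_len(nWells), each = length(subwells)),
                 rep(subwells, nWells)),
    plate = plate,
    well = rep(seq_len(nWells), each = length(subwells)),
    subwell = rep(subwells, nWells),
    class = draws$classes,
    stringsAsFactors = FALSE)
  images <- vector("list", nImg)
  truths <- vector("list", nImg)
  for (i in seq_len(nImg)) {
    w <- generateWell(fixtureSpec(draws$classes[i], seed = draws$seeds[i],
                                  size = size,
                                  subwell = manifest$subwell[i]))
    images[[i]] <- w$image
    truths[[i]] <- w$truth
  }
  names(images) <- names(truths) <- manifest$id
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    manifest$path <- file.path(dir, paste0(manifest$id, ".png"))
    for (i in seq_len(nImg)) writeDropletImage(images[[i]],
                                               manifest$path[i])
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    truthDf <- data.frame(
      id = manifest$id, class = manifest$class,
      crystalArea = vapply(truths, function(t) sum(t$crystalMask),
                           numeric(1)),
      dropletArea = vapply(truths, function(t) sum(t$dropletMask),
                           numeric(1)))
    utils::write.csv(truthDf, file.path(dir, "truth.csv"),
                     row.names = FALSE)
  }
  list(manifest = manifest, images = images, truths = truths)
}

#' Generate empty-plate images for background modelling
#'
#' @param nPerSubwell number of empty wells per subwell position.
#' @param seed RNG seed.
#' @param size image side length.
#' @param subwells subwell position names.
#' @return list with \code{images} and parallel \code{subwells} vector,
#'   ready for [buildBackground()].
#' @export
generateEmptyPlate <- function(nPerSubwell = 4L, seed = 1L, size = 384L,
                               subwells = c("a", "b", "c")) {
  seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, nPerSubwell * length(subwells)))
  imgs <- list(); sw <- character(0)
  k <- 0L
  for (s in subwells) {
    for (i in seq_len(nPerSubwell)) {
      k <- k + 1L
      w <- generateWell(fixtureSpec("fault_empty", seed = seeds[k],
                                    size = size, subwell = s))
      imgs[[k]] <- w$image
      sw <- c(sw, s)
    }
  }
  list(images = imgs, subwells = sw)
}

#' Generate a flat texture patch
#'
#' Renders a droplet-free patch of one texture class (uniform base
#' intensity plus the class texture over the whole patch), for studying
#' filter-bank and texton behaviour in isolation.
#'
#' With \code{rotation} set, the same texture features (needle
#' orientations, speck positions, the band-limited noise field) are
#' rendered in coordinates rotated about the patch centre — emulating a
#' physical rotation of the sample under the imager. This avoids the
#' resampling loss of rotating an already-rasterised patch, which for
#' features near the sampling limit (1-2 px specks) destroys texture
#' content that no descriptor could be invariant to.
#'
#' @param class \code{"clear"}, \code{"precipitate"}, \code{"crystal"} or
#'   \code{"microcrystal_shower"}.
#' @param size patch side length (default 128).
#' @param seed RNG seed; the same seed with a different \code{rotation}
#'   gives the same texture, rotated.
#' @param rotation rotation of the texture in degrees (default 0).
#' @return numeric matrix (0-255).
#' @export
makeTexturePatch <- function(class, size = 128L, seed = 1L,
                             rotation = 0) {
  class <- match.arg(class, c("clear", "precipitate", "crystal",
                              "microcrystal_shower"))
  withr::with_seed(seed, {
    n <- size
    ctr <- (n + 1) / 2
    rot <- rotation * pi / 180
    rotPt <- function(r, c) {
      dr <- r - ctr; dc <- c - ctr
      list(r = ctr + dr * cos(rot) + dc * sin(rot),
           c = ctr - dr * sin(rot) + dc * cos(rot))
    }
    img <- matrix(150, n, n)
    if (class == "precipitate") {
      # band-limited noise on a padded canvas, sampled at rotated
      # coordinates (the field is smooth at sigma 1.2, so bilinear
      # sampling is accurate)
      pad <- ceiling(n * 0.3)
      N <- n + 2L * pad
      noise <- matrix(stats::rnorm(N * N), N, N)
      band <- as.matrix(EBImage::gblur(noise, sigma = 1.2))
      band <- band / stats::sd(band) * 20
      rr <- matrix(seq_len(n), n, n)
      cc <- matrix(seq_len(n), n, n, byrow = TRUE)
      p <- rotPt(rr, cc)
      img <- img + matrix(bilinearSample(band, p$r + pad, p$c + pad), n, n)
    } else if (class == "crystal") {
      for (i in seq_len(max(3L, round(n / 30)))) {
        len <- stats::runif(1, 0.2, 0.6) * n
        wid <- stats::runif(1, 3, 9)
        ang <- stats::runif(1, 0, pi)
        pos <- stats::runif(2, 0.2, 0.8) * n
        p <- rotPt(pos[1L], pos[2L])
        rc <- rectangleMask(n, n, p$r, p$c, len, wid, ang + rot)
        img[rc] <- img[rc] + 80
      }
    } else if (class == "microcrystal_shower") {
      m <- round(0.01 * n * n)
      pr0 <- stats::runif(m, 1, n)
      pc0 <- stats::runif(m, 1, n)
      p <- rotPt(pr0, pc0)
      keep <- p$r >= 1 & p$r <= n & p$c >= 1 & p$c <= n
      sp <- paintSpecks(matrix(FALSE, n, n),
                        round(p$r[keep]), round(p$c[keep]),
                        rep(1L, sum(keep)))
      img[sp] <- img[sp] + 70
    } else {
      rr <- matrix(seq_len(n), n, n)
      cc <- matrix(seq_len(n), n, n, byrow = TRUE)
      img <- img + 10 * rotPt(rr, cc)$r / n
    }
    clamp(img + stats::rnorm(n * n, 0, 2.5), 0, 255)
  })
}
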
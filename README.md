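# mitonet

Single-cell analysis of mitochondrial network morphology from 2D
fluorescence micrographs.

Mitochondria remodel constantly between fragmented and tubular states, and
that morphology differs between cell types, genotypes and stress
conditions. Quantifying it at scale needs three things automated end to
end: isolating individual cells from multi-cell images, binarizing each
cell's mitochondrial network, and reducing the network to numbers. mitonet
implements that stack for 2D RGB micrographs with nuclei in the blue
channel and mitochondria in green or red, for researchers building
morphology datasets large enough for statistical or machine-learning
analysis.

## The methods

**Cell separation.** Nuclei (top-hat → blur → Otsu over non-zero
intensities → open/close → contour fill → size filter) seed 2D Gaussian
distributions N(μ, Σ) over pixel coordinates. The mitochondrial background
is estimated under the nuclei — there is no in-plane mitochondrial signal
inside a nucleus — and removed at mean + 2σ. Nuclei without nearby signal
are dropped as ghost cells. Remaining signal components are linked to
nuclei by expectation-maximization: small touching blobs join their
nucleus wholesale; blobs contacting several nuclei are split pixel-by-pixel
by maximum Gaussian log-likelihood; free blobs join the seed with the best
average per-pixel log-likelihood; seeds are re-estimated after every round
until assignment stabilizes. Outlier linkages are pruned where the squared
Mahalanobis distance of a mitochondrion's centroid to the cell's centroid
distribution exceeds χ²₂(0.95) = 5.99, and cells clipped by the frame are
flagged and exported separately.

**Network segmentation.** For each single-cell image the nuclear zone
serves as background probe: quartile fences (Q1 − 1.5·IQR, Q3 + 1.5·IQR)
discard in-plane outliers, and the clean moments give the signal threshold
mean + 2σ. Optional adaptive correction (AdaMM) divides the image into
tiles and shifts each occupied tile's threshold by a generalized logistic
function of the tile mean, inflected at the background mean — dim tiles
get lower thresholds (recovering faint structure), bright tiles higher
ones.

**Morphometry.** Each binary network yields 31 features per mitochondrion
(23 geometry — area, perimeter, convex hull, solidity, bounding box,
extent, axes, orientation, form factor 4πA/P², densities from the distance
transform, … — plus 8 aggregates of skeleton branch lengths from
topology-preserving thinning) and 110 features per cell (90 = mean, median,
sd of each aggregatable mitochondrion feature; 20 population features
including network solidity, nearest-neighbor spacing, and the box-counting
fractal dimension). Cohort QC flags cells with > 20% IQR-outlier readouts
and prunes multicollinear features by variance inflation factor.

A synthetic-image generator with exhaustive ground truth (elliptical
nuclei, random-walk filaments with Gaussian cross-section, defocused
out-of-plane glow, Gaussian + salt-and-pepper noise, ghost and
edge-truncated cells) backs the test suite for every stage.

## Worked example

Generate a four-cell synthetic image, separate the cells, segment each
network and extract features:

```r
library(mitonet)

sim    <- synth_preset("separated", seed = 42)
caught <- catch_cells(sim$image)
caught$log
#>   nuclei_found         ghosts          cells bad_edge_cells          blobs
#>              4              0              4              0             20
#> blobs_assigned
#>             20

ch <- split_channels(sim$image)
masks <- list()
for (cell in caught$cells) {
  numask <- matrix(FALSE, sim$image$height, sim$image$width)
  numask[cell$nucleus] <- TRUE
  mito <- matrix(0, sim$image$height, sim$image$width)
  mito[cell$mito] <- ch$mito[cell$mito]
  sub <- merge_channels(ch$nuclei * numask, mito, sim$image$mito_channel)
  seg <- segment_cell(sub, nucleus_mask = numask)
  masks[[sprintf("cell_%03d", cell$label)]] <- seg$mask
}

res <- analyze_masks(masks)
dim(res$mitochondria)   # 10 mitochondria x (2 id + 31 feature) columns
#> [1] 10 33
dim(res$cells)          # 4 cells x (2 id + 110 feature) columns
#> [1]   4 112

res$cells[, c("cell_id", "mito_count", "net_area", "net_solidity",
              "fractal_dimension", "mean_branch_length_mean")]
#>    cell_id mito_count net_area net_solidity fractal_dimension mean_branch_length_mean
#> 1 cell_001          3      441        0.237              1.27                    5.07
#> 2 cell_002          3      586        0.236              1.34                   15.05
#> 3 cell_003          1     1136        0.403              1.52                   11.34
#> 4 cell_004          3      656        0.330              1.34                   12.02
```

All 20 above-background blobs were linked to the 4 planted nuclei (no
ghosts, no edge cells in this preset). Each cell's row condenses its
network: `net_area` is total mitochondrial area in px², `net_solidity` the
network area over its convex hull (sparseness of the distribution across
the cell), `fractal_dimension` the box-counting estimate of geometric
complexity (1 = line-like, 2 = space-filling), and
`mean_branch_length_mean` the per-cell mean of each mitochondrion's mean
skeleton branch length in px. `write_table()` exports the tables as
CSV/TSV after validating every value is finite.

The same workflow is scriptable from a shell via the thin wrapper in
`inst/cli/mitonet.R` (`synth`, `catch-cells`, `catch-mito`, `compare`,
`analyze`, `qc`, `run`), and `run_pipeline()` drives whole directories
with a JSON config.

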
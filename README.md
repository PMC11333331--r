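# phytoniche

Habitat suitability modelling and phytochemical quality zoning for
medicinal plants.

## The problem

The quality of a herbal medicine such as *Lonicera japonica* Flos
(honeysuckle flower) depends on secondary metabolites — chlorogenic acid,
rutin, hyperoside, cynaroside, isochlorogenic acid A — whose accumulation
tracks the ecological conditions of the growing region. Two questions
follow: *where can the species grow* (and how will that change under
future climate scenarios), and *where is its chemical quality highest*?
`phytoniche` answers both in one pipeline, aimed at researchers in
medicinal-plant resource science and ecological niche modelling.

## What is inside

* **Maximum-entropy distribution model**, written from scratch: the Gibbs
  distribution over background cells
  `q(x) = exp(Σ λ_j f_j(x)) / Z`
  fitted by maximizing the L1-penalized mean presence log-probability
  `(1/m) Σ log q(x_i) − Σ β_j |λ_j|`
  with linear, quadratic, product and hinge features, the canonical
  per-class regularization schedule, bootstrap replication, and the
  entropy-based logistic output `p = e^H q / (1 + e^H q)`.
* **Evaluation**: pair-counting AUC, percent contributions, permutation
  importance, jackknife training gains, marginal response curves.
* **Zoning**: four suitability grades (fixed 0.2/0.4/0.6 edges or exact
  Fisher–Jenks natural breaks), latitude-corrected class areas in km²,
  percent change between scenarios.
* **Centroid migration**: area-weighted range centroids and haversine
  distances (R = 6371 km) with bearings.
* **HPLC fingerprints**: peak detection, retention-time correction,
  common-peak matching, reference fingerprint, congruence (cosine)
  similarity matrix, method-validation RSDs, external-standard
  quantification.
* **Quality zoning**: stepwise environment–metabolite regression,
  compound-factor correlation tables, predicted content surfaces, and the
  suitability-masked quality overlay.
* **Synthetic generators** (Gaussian random fields, occurrences from a
  known suitability law, chromatograms with planted peaks) so the whole
  chain is testable without any download.

Data containers are S4 classes (`RasterGrid`, `EnvStack`, `OccurrenceSet`,
`MaxentModel`, `CommonPeakMatrix`, ...) with validity checks, accessors and
`show` methods; rasters travel as ESRI ASCII grids, occurrences as
`species,longitude,latitude` CSV.

## Worked example

```r
library(phytoniche)

# centroid migration between published range centroids
current <- c(111.881004, 32.083149)
scenarios <- list(
  "2050s-SSP126" = c(114.613104, 32.35066),
  "2090s-SSP126" = c(112.161545, 30.829002),
  "2050s-SSP370" = c(110.682713, 31.722339),
  "2090s-SSP370" = c(110.507134, 30.702936))
migrationTable(current, scenarios)
#>       scenario     lon     lat distance_km bearing_deg
#> 1 2050s-SSP126 114.613 32.3507     258.730     82.6712
#> 2 2090s-SSP126 112.162 30.8290     141.971    169.1234
#> 3 2050s-SSP370 110.683 31.7223     120.020    250.7888
#> 4 2090s-SSP370 110.507 30.7029     201.388    220.7142
```

The distances radiate from the current centroid; 258.73 km eastward for
the 2050s low-emission scenario, 120.02 km westward for 2050s-SSP370, and
so on.

```r
# a synthetic scene with a known suitability law, end to end
stack <- makeEnvStack(k = 5, nrows = 64, ncols = 64, seed = 7,
                      names = c("bio4", "bio6", "bio12", "elev", "srad2"))
occ <- simulateOccurrences(stack, trueBeta = c(bio6 = 3, bio12 = 1.2),
                           intercept = -6, n = 298, seed = 42)
ens <- bootstrapEnsemble(occ, stack, reps = 12, seed = 5,
                         nBackground = 1500,
                         config = list(nKnots = 10, maxIter = 300))
mean(ens$testAUC)
#> [1] 0.926

classifySuitability(ens$meanRaster)
#> SuitabilityClassMap: breaks 0.2 / 0.4 / 0.6
#>   no            91808.4 km2
#>   low           13950.4 km2
#>   medium         8361.1 km2
#>   high           3584.4 km2
```

Held-out presences are separated from background with mean test AUC 0.93
(the planted law drives ~6% of the landscape to high suitability, and the
classified map recovers that share), and `jackknifeGains()` ranks the
dominant planted driver `bio6` first. `runPipeline(outputDir)` runs every
stage — screening, ensemble, zoning, centroids, fingerprints, quality
overlay — and writes the artifact set with a run log.

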
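# genonav

**genonav** is a genotype-exploration engine for population-scale variant
data, aimed at researchers who need to sift VCF or HapMap genotype panels —
thousands of individuals, SNPs and indels, SnpEff annotations — without
writing ad-hoc scripts for every question.  It imports genotype files into a
marker-oriented store and answers, in real time:

* *How many variants match these criteria?* (`count_variants`)
* *Show them to me, sorted and paginated.* (`find_variants`,
  `variant_detail`)
* *Write the selection out in a standard format.* (`export_variants`, seven
  formats: VCF, Eigenstrat, GFF3, BED, HapMap, DARwin, PLINK)
* *How are they distributed along each chromosome?* (`variant_density`)

Filters combine **variant features** — type, sequence, position range,
number of known alleles, SnpEff effect and gene name (both the `EFF` and
`ANN` field generations are auto-detected) — with **genotype-level
criteria** over the selected individuals:

* genotype patterns (twelve predicates such as *all same*, *at least one
  heterozygous*, *mostly same*, *without abnormal heterozygosity*);
* per-sample GQ/DP thresholds, below which a call is treated as missing
  data — the core masking rule of the engine;
* a maximum missing-data ratio (default 100 %, i.e. accepting all data);
* a minor-allele-frequency range (default 0–50 %); for a bi-allelic variant
  with allele counts $c_0, c_1$ over the called allele slots of the selected
  individuals, $\mathrm{MAF} = \min(c_0, c_1) / (c_0 + c_1) \le 0.5$.

Queries run as a two-step strategy: a fast indexed pre-filter on variant
features, then genotype-level evaluation split into evenly sized chunks
(via an ID subset or the landmark *tag index*), with per-chunk progress,
abort, and a count cache invalidated on import.  An individual genotyped in
several runs is consolidated to one genotype per variant (majority rule,
seeded tie-break), and phasing is preserved across filtered-out positions:
exported flanking records still share their phase set (`PS`) even when the
variants between them were filtered away.

A deterministic synthetic-fixture generator (`fixture_spec`,
`generate_fixture`) produces VCF/HapMap panels with a machine-readable truth
table, so the whole engine is testable offline.

## Worked example

```r
library(genonav)

# a deterministic synthetic panel: 200 variants x 12 individuals, annotated
fs <- fixture_spec(n_variants = 200, n_individuals = 12, n_sequences = 2,
                   missing_rate = 0.05, phased_fraction = 0.3,
                   annotation_style = "ANN", seed = 42)
fx <- generate_fixture(fs, "demo-data")

st <- open_store("demo-store", "rice")
import_vcf(st, fx$vcf, "panel", "run1")
#> <import: 200 variants, 12 new samples, annotations: ANN>

count_variants(st, "panel")          # pass-all defaults
#> [1] 200

spec <- filter_spec(sequences = "chr1", maf_range = c(0.1, 0.5),
                    max_missing_ratio = 0.2, pattern = "at_least_one_het",
                    min_gq = 20)
count_variants(st, "panel", spec)
#> [1] 65

find_variants(st, "panel", spec, page = 1, page_size = 5)
#> <result page 1 (5 of 65 rows, sorted by position asc)>
#>        variant_id sequence start  stop alleles                effect    gene
#> 1:       var00001     chr1   103   103     G,C        intron_variant GENE012
#> 2:       var00003     chr1  8946  8946     C,A upstream_gene_variant GENE005
#> 3:       var00005     chr1 25490 25490     G,A    synonymous_variant GENE017
#> 4: chr1:25851:C:G     chr1 25851 25851     C,G    frameshift_variant GENE001
#> 5: chr1:46208:T:C     chr1 46208 46208     T,C           stop_gained GENE017

export_variants(st, "panel", spec, export_spec("PLINK", "demo-export/sel"))
# writes demo-export/sel.ped and demo-export/sel.map

head(variant_density(st, "panel", spec, bin_width = 250000), 4)
#>    sequence bin_start bin_end variant_type count
#> 1:     chr1         1  250000        INDEL     0
#> 2:     chr1    250001  500000        INDEL     0
#> 3:     chr1    500001  750000        INDEL     2
#> 4:     chr1    750001  986522        INDEL     0
```

The counts read as: of the 200 variants, 65 on chr1 are bi-allelic with MAF
in 10–50 %, have at most 20 % missing data once calls with GQ < 20 are
masked, and show at least one heterozygous individual.  The density table
histograms those 65 by position and variant type.

The same operations are available from a shell via the bundled CLI
(`inst/cli/genonav`): `import`, `tag`, `count`, `find`, `detail`, `export`,
`density`, `fixture`, `list`, with `--json` output for scripting.

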
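# Pollination biodiversity dictionary, v1.
# Terms commonly used in written descriptions of flower visitation and
# pollen transfer. Matching is exact on lowercased surface forms (no
# stemming), so derived and inflected forms are listed explicitly.
# One term per line; "#" lines are comments.
pollinate
pollinates
pollinated
pollination
pollinator
pollinators
pollen
nectar
nectaries
flower
flowers
flowering
floral
visit
visits
visited
visitation
visitor
visitors
anther
anthers
stigma
style
corolla
inflorescence
inflorescences
anthesis
bloom
blooms
blooming
forage
foraging
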
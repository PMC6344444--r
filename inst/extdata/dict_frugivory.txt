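# Frugivory biodiversity dictionary, v1.
# Terms commonly used in written descriptions of fruit-eating interactions
# and the seed dispersal they mediate. Matching is exact on lowercased
# surface forms (no stemming), so derived and inflected forms are listed
# explicitly. One term per line; "#" lines are comments.
fruit
fruits
fruiting
eat
eats
eaten
ate
eating
feed
feeds
feeding
fed
consume
consumes
consumed
consumption
ingest
ingests
ingested
ingestion
swallow
swallows
swallowed
swallowing
disperse
disperses
dispersed
dispersal
disperser
dispersers
frugivore
frugivores
frugivorous
frugivory
seed
seeds
pulp
ripe
unripe
regurgitate
regurgitated
defecate
defecated
defecation
gut
diet
dietary
forage
foraged
foraging
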
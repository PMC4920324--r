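region
North America
Central America and Mexico
Caribbean
Andean South America
Tropical South America
Temperate South America
Northwest Europe
Southwest Europe
Northeast Europe
Southeast Europe
South and East Mediterranean
West Asia
Central Asia
South Asia
East Asia
Southeast Asia
West Africa
Central Africa
East Africa
Southern Africa
Indian Ocean Islands
Australia and New Zealand
Pacific Islands
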
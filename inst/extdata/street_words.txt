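Meadow
Birch
Oakfield
Ashworth
Harrow
Elmwood
Hazel
Willow
Bramble
Foxglove
Heather
Juniper
Larkspur
Maple
Nettleton
Orchard
Primrose
Rowan
Sycamore
Thistle
Wren
Alder
Bluebell
Chestnut
Dunmore
Fernlea
Garnet
Holly
Ivybridge
Kestrel
Linden
Mulberry
Nightingale
Osprey
Pembroke
Quarry
Redwood
Stanmore
Tamworth
Verney
Walnut
Yewtree
Aldridge
Bancroft
Calder
Denholm
Eastcote
Farleigh
Gresham
Hartwell
Ingram
Jesmond
Kirkstall
Lambourn
Marsden
Norbury
Ormond
Pelham
Ravensworth
Sedgwick
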
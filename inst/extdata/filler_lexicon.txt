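lorem
ipsum
dolor
sit
amet
consectetur
adipiscing
elit
sed
do
eiusmod
tempor
incididunt
ut
labore
et
dolore
magna
aliqua
enim
ad
minim
veniam
quis
nostrud
exercitation
ullamco
laboris
nisi
aliquip
ex
ea
commodo
consequat
duis
aute
irure
in
reprehenderit
voluptate
velit
esse
cillum
eu
fugiat
nulla
pariatur
excepteur
sint
occaecat
cupidatat
non
proident
sunt
culpa
qui
officia
deserunt
mollit
anim
id
est
laborum
perspiciatis
unde
omnis
iste
natus
error
voluptatem
accusantium
doloremque
laudantium
totam
rem
aperiam
eaque
ipsa
quae
ab
illo
inventore
veritatis
quasi
architecto
beatae
vitae
dicta
explicabo
nemo
ipsam
quia
voluptas
aspernatur
aut
odit
fugit
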
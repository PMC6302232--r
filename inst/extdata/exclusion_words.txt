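# Common English and Spanish nouns, verbs and adjectives that collide
# with place names; bare location fields equal to one of these are
# never mapped. Editable; one lowercase word per line.
time
year
people
way
day
man
thing
woman
life
child
world
school
state
family
student
group
country
problem
hand
part
place
case
week
company
system
program
question
work
government
number
night
point
home
water
room
mother
area
money
story
fact
month
lot
right
study
book
eye
job
word
business
issue
side
kind
head
house
service
friend
father
power
hour
game
line
end
member
law
car
city
community
name
president
team
minute
idea
kid
body
information
back
parent
face
others
level
office
door
health
person
art
war
history
party
result
change
morning
reason
research
girl
guy
moment
air
teacher
force
education
be
have
do
say
go
can
get
would
make
know
will
think
take
see
come
could
want
look
use
find
give
tell
work
may
should
call
try
ask
need
feel
become
leave
put
mean
keep
let
begin
seem
help
talk
turn
start
show
hear
play
run
move
like
live
believe
hold
bring
happen
write
provide
sit
stand
lose
pay
meet
include
continue
set
learn
lead
understand
watch
follow
stop
create
speak
read
reading
allow
add
spend
grow
open
walk
win
offer
remember
love
consider
appear
buy
wait
serve
die
send
expect
build
stay
fall
cut
reach
kill
remain
good
new
first
last
long
great
little
own
other
old
big
high
different
small
large
next
early
young
important
few
public
bad
same
able
mobile
free
full
low
sweet
golden
union
liberty
hope
pleasant
orange
phoenix
independence
riverside
eagle
surprise
normal
superior
commerce
industry
enterprise
friendship
harmony
midway
center
centro
casa
tiempo
vida
mundo
dia
hombre
mujer
agua
tierra
ciudad
nombre
parte
lugar
trabajo
punto
forma
caso
mano
ser
estar
tener
hacer
poder
decir
ir
ver
dar
saber
querer
llegar
pasar
deber
poner
parecer
quedar
creer
hablar
llevar
dejar
seguir
encontrar
llamar
venir
pensar
salir
volver
tomar
conocer
vivir
sentir
mirar
contar
empezar
esperar
buscar
bueno
nuevo
primero
grande
alto
bajo
largo
pequeno
mismo
mejor
blanco
verde
azul
rico
libre
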
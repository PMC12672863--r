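The kitchen window is open and the curtains are moving a little in the
breeze. A woman stands at the sink drying a plate while the water runs over
the edge of the basin and spreads in a wide puddle across the floor. She
does not seem to notice the water at her feet because she is looking out at
the garden. Behind her a boy has climbed onto a wooden stool to reach the
cookie jar on the top shelf of the cupboard. The stool is tipping to one
side and the boy is about to fall, but he keeps one hand in the jar and
passes a cookie down to his sister. The little girl stands beside the stool
with her hand raised, asking for another cookie, and she is laughing because
she thinks the whole thing is a game. The cupboard door hangs open above
them. On the counter there are two cups and a dish that somebody left there
after lunch. Outside the window you can see a path that curves past a
flower bed and a low hedge, and the neighbour's house shows over the fence.

It was a bright morning and the family had been busy since early. The
mother said she would wash the dishes before the guests arrived, and the
children promised to help, though they slipped away to the pantry the
moment her back was turned. The boy wanted the cookies because they were
fresh from the oven the day before, round and brown with sugar on top. He
told his sister to keep watch, but she watched him instead, and neither of
them heard the tap still running. Water kept flowing over the sink and
dripping onto the tiles with a steady sound, and still the woman dried the
same plate, moving the cloth in slow circles while her thoughts wandered
somewhere far from the kitchen.

When people describe a picture like this one they usually begin with the
people in it. They say a mother is standing by the sink, a boy is on a
stool, a girl is reaching up. Then they notice the small troubles
everywhere, the overflowing water, the tilting stool, the open cupboard,
and the story assembles itself out of these details. Some speakers give
long and winding accounts with many asides, and others offer only a few
short phrases, a boy, a jar, some water on the floor. The way a person
moves through the scene, what they name first, where they pause, and how
they connect one thing to the next can say as much about the speaker as
about the picture itself.

The afternoon light fell across the table where an old man sat with his
letters. He read each one slowly, holding the paper close, and now and then
he set a page down to look out at the yard where the dog slept under the
apple tree. He remembered summers when the children were small and the
house was loud from morning to night. Someone was always running through
the hall, someone was always calling from the stairs, and the kettle seemed
never to be off the stove. These days the rooms kept their quiet. He wrote
his replies in a careful hand, signed his name at the bottom, and stacked
the envelopes by the door so he would remember to post them on his walk.

She told the story again at dinner, the one about the market and the crate
of oranges. Everyone had heard it before and everyone wanted to hear it
again, because each telling gathered some new decoration. This time the
crate was heavier, the street was steeper, and the stray cat that had
followed her home grew bolder and hungrier than ever. Her husband laughed
in the same places he always laughed. The children asked the same questions
they always asked, where did the cat sleep, did it ever go home, and she
answered them patiently while the soup cooled in the pot between them.

In the morning the fog lay along the river so thick that the far bank
disappeared, and the fishermen walked down to their boats like men wading
into a cloud. By noon the sun had burned it away and the water showed every
stone on the bottom. A heron stood in the shallows for an hour without
moving, then took one slow step and waited again. Two boys skipped flat
stones from the gravel bar and counted the hops out loud, five, six, seven,
and argued happily about whose throw had gone the farthest before they ran
off along the path toward the bridge and the town beyond it.

The nurse asked him to describe his morning, and he began with the
garden, because the garden came first. He had watered the beans and tied
the tomatoes to their stakes, and he had found the first ripe strawberry
hiding under a leaf. He described the walk to the shop, the neighbour who
waved from her porch, the bread he bought and the coffee he drank at the
counter while the radio gave the weather. He spoke slowly but steadily,
finding each word in its turn, and when he could not find a word he went
around it, the thing you cut bread with, the man who brings the post, and
carried on with his account until the story reached the present moment and
settled there, complete.
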